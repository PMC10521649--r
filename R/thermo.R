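#' Gas constant, kJ/(mol K)
#' @keywords internal
R_GAS <- 8.314462618e-3

#' Convert a standard Gibbs energy to RT units
#'
#' @param delta_g_kJ_mol Transformed standard reaction Gibbs energy, kJ/mol.
#' @param temperature_K Temperature in Kelvin (default 298.15).
#' @return The dimensionless energy `delta_g / (R * T)`.
#' @export
gibbs_to_rt <- function(delta_g_kJ_mol, temperature_K = 298.15) {
  if (temperature_K <= 0) stop("temperature must be positive", call. = FALSE)
  if (any(!is.finite(delta_g_kJ_mol)))
    stop("non-finite Gibbs energy", call. = FALSE)
  delta_g_kJ_mol / (R_GAS * temperature_K)
}

#' Default physiological concentration ranges for central metabolites
#'
#' The broad search box is 1 uM -- 10 mM for every metabolite; fifteen
#' central metabolites and cofactors are confined to narrower,
#' literature-typical physiological ranges. These shipped values are a
#' curated stand-in (replaceable via the `overrides` argument of
#' [build_concentration_bounds()] or a TSV with columns
#' `metabolite_id`, `c_min_molar`, `c_max_molar`).
#'
#' @return A data frame with columns `id`, `c_min`, `c_max` (mol/L).
#' @export
default_metabolite_ranges <- function() {
  data.frame(
    id    = c("atp", "adp", "amp", "pi", "nad", "nadh", "nadp", "nadph",
              "coa", "glutamate", "akg", "pep", "pyruvate", "3pg", "fbp"),
    c_min = c(1e-3, 1e-4, 1e-4, 1e-3, 1e-3, 3e-5, 1e-6, 1e-5,
              1e-4, 1e-2, 1e-4, 1e-5, 5e-5, 1e-4, 1e-3),
    c_max = c(1e-2, 1e-3, 1e-3, 1e-2, 5e-3, 5e-4, 5e-4, 5e-4,
              1e-3, 1.5e-1, 1e-3, 5e-4, 5e-3, 5e-3, 2e-2),
    stringsAsFactors = FALSE)
}

#' Build per-metabolite log-concentration boxes
#'
#' Every non-exempt metabolite receives the default box
#' `[ln c_min_default, ln c_max_default]` (1 uM to 10 mM) unless overridden.
#'
#' @param network A `metabolic_network` or `directed_network`.
#' @param overrides Data frame with columns `id`, `c_min`, `c_max`
#'   (mol/L), or `NULL`. All ids must exist in the network.
#' @param c_min_default,c_max_default Default bounds, mol/L.
#' @return A list with named numeric vectors `ln_c_min` and `ln_c_max`
#'   over non-exempt metabolites.
#' @export
build_concentration_bounds <- function(network, overrides = NULL,
                                       c_min_default = 1e-6,
                                       c_max_default = 1e-2) {
  ids <- setdiff(metabolite_ids(network), exempt_ids(network))
  ln_min <- stats::setNames(rep(log(c_min_default), length(ids)), ids)
  ln_max <- stats::setNames(rep(log(c_max_default), length(ids)), ids)
  if (!is.null(overrides) && nrow(overrides)) {
    unknown <- setdiff(overrides$id, ids)
    if (length(unknown))
      stop("override for unknown or exempt metabolite: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    if (any(overrides$c_min <= 0) || any(overrides$c_max <= 0))
      stop("concentration bounds must be positive", call. = FALSE)
    if (any(overrides$c_min > overrides$c_max))
      stop("c_min > c_max for: ",
           paste(overrides$id[overrides$c_min > overrides$c_max], collapse = ", "),
           call. = FALSE)
    ln_min[overrides$id] <- log(overrides$c_min)
    ln_max[overrides$id] <- log(overrides$c_max)
  }
  list(ln_c_min = ln_min, ln_c_max = ln_max)
}

#' Read a concentration-override TSV
#'
#' Columns: `metabolite_id`, `c_min_molar`, `c_max_molar`.
#'
#' @param path TSV path.
#' @return Data frame in the [build_concentration_bounds()] override format.
#' @export
read_concentration_overrides <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  data.frame(id = tab$metabolite_id, c_min = tab$c_min_molar,
             c_max = tab$c_max_molar, stringsAsFactors = FALSE)
}

#' Big-M constant for one directed reaction
#'
#' Returns `max(0, g0 + max_x (S^T x) + margin)` over the concentration box,
#' which guarantees the linearised second-law constraint
#' `-g0 - S^T x + M (1 - z) >= 0` is vacuous whenever `z = 0`.
#' Thermodynamically exempt metabolites contribute nothing to `S^T x`.
#'
#' @param stoich Named signed coefficient vector of the directed reaction.
#' @param g0 Standard Gibbs energy in RT units.
#' @param ln_c_min,ln_c_max Named log-concentration bounds.
#' @param margin Safety margin in RT units (default 1).
#' @param exempt Metabolite ids excluded from the concentration term;
#'   participants neither bounded nor exempt are an error.
#' @return A non-negative scalar.
#' @export
compute_big_m <- function(stoich, g0, ln_c_min, ln_c_max, margin = 1,
                          exempt = character()) {
  ids <- setdiff(names(stoich), exempt)
  missing <- setdiff(ids, names(ln_c_min))
  if (length(missing))
    stop("missing concentration bound for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  s <- stoich[ids]
  span <- sum(ifelse(s > 0, s * ln_c_max[ids], s * ln_c_min[ids]))
  max(0, g0 + span + margin)
}

#' Driving force of a directed reaction at given log-concentrations
#'
#' The driving force is `-g0 - S^T x` in RT units; a positive value means
#' the reaction is exergonic at `x`. Exempt metabolites are skipped.
#'
#' @param stoich Named signed coefficient vector.
#' @param g0 Standard Gibbs energy in RT units.
#' @param x Named log-concentration vector; must cover all non-exempt
#'   participants.
#' @param exempt Ids excluded from the concentration term.
#' @return A scalar in RT units.
#' @export
driving_force <- function(stoich, g0, x, exempt = character()) {
  ids <- setdiff(names(stoich), exempt)
  missing <- setdiff(ids, names(x))
  if (length(missing))
    stop("missing concentration for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  -g0 - sum(stoich[ids] * x[ids])
}

#' Assemble thermodynamic parameters for a directed network
#'
#' Collects per-directed-reaction standard Gibbs energies (RT units),
#' the log-concentration box, and per-reaction big-M constants.
#'
#' @param directed A `directed_network`.
#' @param bounds Output of [build_concentration_bounds()]; defaults to the
#'   plain 1 uM -- 10 mM box.
#' @param margin Big-M margin in RT units.
#' @return An object of class `"thermo_params"`.
#' @export
thermo_params <- function(directed, bounds = NULL, margin = 1) {
  if (is.null(bounds)) bounds <- build_concentration_bounds(directed)
  stopifnot(all(bounds$ln_c_min <= bounds$ln_c_max))
  ex <- exempt_ids(directed)
  g0 <- vapply(directed$reactions, `[[`, numeric(1), "g0")
  big_m <- vapply(directed$reactions, function(d) {
    if (is.na(d$g0)) return(NA_real_)
    compute_big_m(d$stoich, d$g0, bounds$ln_c_min, bounds$ln_c_max, margin,
                  exempt = ex)
  }, numeric(1))
  structure(list(g0 = g0, ln_c_min = bounds$ln_c_min, ln_c_max = bounds$ln_c_max,
                 big_m = big_m, margin = margin, exempt = ex,
                 temperature_K = directed$temperature_K %||% 298.15),
            class = "thermo_params")
}

#' @export
print.thermo_params <- function(x, ...) {
  cat("Thermodynamic parameters: ", sum(!is.na(x$g0)), " constrained reactions, ",
      length(x$ln_c_min), " bounded metabolites\n", sep = "")
  cat("Box span (default metabolite): ",
      format(max(x$ln_c_max) - min(x$ln_c_min)), " RT\n", sep = "")
  invisible(x)
}
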