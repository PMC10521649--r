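#' Enumeration configuration
#'
#' Defaults follow the study conditions of the pathway search: flux cap
#' `beta = 10`, at most 10 solutions per ATP yield, integer cuts of radius
#' 2 (subsequent solutions must differ in more than 2 indicator positions),
#' and an ATP-yield scan over -2..2.
#'
#' @param beta Positive flux cap for each directed reaction.
#' @param max_solutions Stop after this many solutions per yield.
#' @param cut_radius Non-negative integer-cut radius.
#' @param atp_yields Integer vector of yields to scan.
#' @param solver Backend name; `"highs"` (HiGHS via scipy) is the one
#'   shipped backend.
#' @param time_limit_s Optional per-solve time limit, seconds.
#' @param tolerance Numerical tolerance for flux support and verification.
#' @param flux_epsilon Minimum rate forced through an active reaction
#'   (`flux_epsilon * z_i <= v_i`); ties the indicator set to the actual
#'   flux support so enumerated solutions cannot carry zero-flux padding.
#' @return A list of class `"enumeration_config"`.
#' @export
enumeration_config <- function(beta = 10, max_solutions = 10L, cut_radius = 2L,
                               atp_yields = -2:2, solver = "highs",
                               time_limit_s = NULL, tolerance = 1e-6,
                               flux_epsilon = 1e-3) {
  stopifnot(beta > 0, max_solutions >= 1, cut_radius >= 0, flux_epsilon >= 0,
            flux_epsilon < beta)
  structure(list(beta = beta, max_solutions = as.integer(max_solutions),
                 cut_radius = as.integer(cut_radius),
                 atp_yields = as.integer(atp_yields), solver = solver,
                 time_limit_s = time_limit_s, tolerance = tolerance,
                 flux_epsilon = flux_epsilon),
            class = "enumeration_config")
}

#' Build the minimal-pathway MILP
#'
#' Variables: a rate `v_i` in `[0, beta]` and a binary indicator `z_i` per
#' directed reaction, and a log-concentration `x_j` in its box per
#' non-exempt metabolite. Constraints: steady-state mass balance with the
#' objective rate fixed at -1; the linearised second law
#' `-g0_i - (S^T x)_i + M_i (1 - z_i) >= 0`; indicator coupling
#' `flux_epsilon * z_i <= v_i <= beta * z_i`; direction exclusivity
#' `z_fwd + z_bwd <= 1`; plus any integer cuts. Objective: minimise the
#' number of active reactions, `sum(z)`.
#'
#' @param directed A `directed_network`.
#' @param thermo A [thermo_params()] object.
#' @param config An [enumeration_config()].
#' @return An object of class `"milp_problem"`.
#' @export
build_milp <- function(directed, thermo, config = enumeration_config()) {
  rxn_ids <- names(directed$reactions)
  m <- length(rxn_ids)
  if (m == 0L) stop("empty directed network", call. = FALSE)
  met_ids <- metabolite_ids(directed)
  x_ids <- names(thermo$ln_c_min)
  p <- length(x_ids)
  nv <- 2L * m + p                      # [v | z | x]
  iv <- seq_len(m); iz <- m + seq_len(m); ix <- 2L * m + seq_len(p)

  # mass balance: S v = s_obj (v_obj = -1 moved to the right-hand side)
  S <- matrix(0, length(met_ids), m, dimnames = list(met_ids, rxn_ids))
  for (d in directed$reactions) S[names(d$stoich), d$id] <- d$stoich
  A_eq <- cbind(S, matrix(0, length(met_ids), m + p))
  b_eq <- stats::setNames(rep(0, length(met_ids)), met_ids)
  ob <- directed$objective$stoich
  b_eq[names(ob)] <- ob

  rows_ub <- list(); b_ub <- numeric()
  add_row <- function(idx, val, rhs) {
    r <- numeric(nv); r[idx] <- val
    rows_ub[[length(rows_ub) + 1L]] <<- r
    b_ub[length(b_ub) + 1L] <<- rhs
  }
  # second law, active case: (S^T x)_i + M_i z_i <= M_i - g0_i
  for (k in seq_len(m)) {
    d <- directed$reactions[[k]]
    if (is.na(thermo$g0[[d$id]])) next
    ids <- intersect(names(d$stoich), x_ids)
    add_row(c(ix[match(ids, x_ids)], iz[k]),
            c(d$stoich[ids], thermo$big_m[[d$id]]),
            thermo$big_m[[d$id]] - thermo$g0[[d$id]])
  }
  # indicator coupling
  for (k in seq_len(m)) {
    add_row(c(iv[k], iz[k]), c(1, -config$beta), 0)
    if (config$flux_epsilon > 0)
      add_row(c(iv[k], iz[k]), c(-1, config$flux_epsilon), 0)
  }
  # direction exclusivity
  for (pair in directed$pairing) {
    if (length(pair) == 2L)
      add_row(iz[match(pair, rxn_ids)], c(1, 1), 1)
  }
  A_ub <- do.call(rbind, rows_ub)

  lb <- c(rep(0, m), rep(0, m), thermo$ln_c_min[x_ids])
  ub <- c(rep(config$beta, m), rep(1, m), thermo$ln_c_max[x_ids])
  structure(list(
    obj = c(rep(0, m), rep(1, m), rep(0, p)),
    A_eq = A_eq, b_eq = unname(b_eq), A_ub = A_ub, b_ub = b_ub,
    lb = lb, ub = ub,
    integrality = c(rep(0L, m), rep(1L, m), rep(0L, p)),
    rxn_ids = rxn_ids, x_ids = x_ids,
    directed = directed, thermo = thermo, config = config,
    cuts = list()), class = "milp_problem")
}

#' Add a radius-limited integer cut
#'
#' Appends the constraint
#' `sum_{i in A} (1 - z_i) + sum_{i not in A} z_i >= radius + 1`
#' for the solution's active set `A`, so subsequent solutions must differ
#' from `A` in more than `radius` indicator positions.
#'
#' @param problem A `milp_problem`.
#' @param solution A `pathway_solution` from this problem's variable space.
#' @param radius Non-negative integer radius.
#' @return The problem with one more cut in its pool.
#' @export
add_integer_cut <- function(problem, solution, radius = 2L) {
  active <- solution$active_set
  unknown <- setdiff(active, problem$rxn_ids)
  if (length(unknown))
    stop("cut references unknown directed reaction: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  problem$cuts[[length(problem$cuts) + 1L]] <-
    list(active = active, radius = as.integer(radius))
  problem
}

cut_rows <- function(problem) {
  m <- length(problem$rxn_ids)
  nv <- length(problem$obj)
  if (!length(problem$cuts)) return(list(A = NULL, b = numeric()))
  A <- matrix(0, length(problem$cuts), nv)
  b <- numeric(length(problem$cuts))
  for (k in seq_along(problem$cuts)) {
    cut <- problem$cuts[[k]]
    in_A <- problem$rxn_ids %in% cut$active
    # sum_A z - sum_!A z <= |A| - radius - 1
    A[k, m + seq_len(m)] <- ifelse(in_A, 1, -1)
    b[k] <- sum(in_A) - cut$radius - 1L
  }
  list(A = A, b = b)
}

#' Solve the MILP for one minimum-reaction pathway
#'
#' @param problem A `milp_problem` (including its current cut pool).
#' @param config Optional [enumeration_config()] override.
#' @return On success, a `pathway_solution` with the active set, fluxes,
#'   log-concentrations and cardinality; otherwise a list of class
#'   `"milp_status"` with `status` one of `"infeasible"`, `"time_limit"`,
#'   `"unbounded"`, `"failed"`.
#' @export
solve_min_pathway <- function(problem, config = problem$config) {
  cuts <- cut_rows(problem)
  A_ub <- rbind(problem$A_ub, cuts$A)
  b_ub <- c(problem$b_ub, cuts$b)
  res <- milp_solve_backend(problem$obj, problem$A_eq, problem$b_eq, A_ub, b_ub,
                            problem$lb, problem$ub, problem$integrality,
                            solver = config$solver,
                            time_limit_s = config$time_limit_s)
  if (res$status != "optimal")
    return(structure(list(status = res$status), class = "milp_status"))
  m <- length(problem$rxn_ids)
  v <- stats::setNames(res$x[seq_len(m)], problem$rxn_ids)
  z <- stats::setNames(round(res$x[m + seq_len(m)]), problem$rxn_ids)
  x <- stats::setNames(res$x[2L * m + seq_along(problem$x_ids)], problem$x_ids)
  active <- problem$rxn_ids[z > 0.5]
  structure(list(active_set = active, fluxes = v, ln_concentrations = x,
                 atp_yield = attr(problem$directed, "atp_yield"),
                 cardinality = length(active), objective_value = res$fun),
            class = "pathway_solution")
}

#' @export
print.pathway_solution <- function(x, ...) {
  cat("Pathway solution: ", x$cardinality, " active reactions",
      if (!is.null(x$atp_yield)) paste0(" (ATP yield ", x$atp_yield, ")"),
      "\n  ", paste(sort(x$active_set), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# ---- solver backend ---------------------------------------------------------

the_backend <- new.env(parent = emptyenv())

scipy_optimize <- function() {
  if (is.null(the_backend$sp)) {
    if (!reticulate::py_available(initialize = TRUE))
      stop("no usable Python for the HiGHS backend; set RETICULATE_PYTHON",
           call. = FALSE)
    the_backend$sp <- reticulate::import("scipy.optimize", delay_load = FALSE)
    the_backend$np <- reticulate::import("numpy", delay_load = FALSE)
  }
  the_backend
}

#' Low-level MILP solve
#'
#' Minimal pluggable surface: minimise `c'y` subject to `A_eq y = b_eq`,
#' `A_ub y <= b_ub`, `lb <= y <= ub`, with `integrality` marking binary /
#' integer entries. The shipped backend is HiGHS through scipy.
#'
#' @param obj,A_eq,b_eq,A_ub,b_ub,lb,ub,integrality Problem data.
#' @param solver Backend name (only `"highs"`).
#' @param time_limit_s Optional time limit.
#' @return List with `status` (`"optimal"`, `"infeasible"`, `"time_limit"`,
#'   `"unbounded"`, `"failed"`), solution `x` and objective `fun`.
#' @keywords internal
milp_solve_backend <- function(obj, A_eq, b_eq, A_ub, b_ub, lb, ub, integrality,
                               solver = "highs", time_limit_s = NULL) {
  if (!identical(solver, "highs"))
    stop("unknown solver backend '", solver, "'", call. = FALSE)
  be <- scipy_optimize()
  cons <- list()
  if (!is.null(A_eq) && nrow(A_eq))
    cons[[length(cons) + 1L]] <- be$sp$LinearConstraint(A_eq, b_eq, b_eq)
  if (!is.null(A_ub) && nrow(A_ub))
    cons[[length(cons) + 1L]] <- be$sp$LinearConstraint(
      A_ub, rep(-Inf, length(b_ub)), b_ub)
  opts <- list(mip_rel_gap = 0)
  if (!is.null(time_limit_s)) opts$time_limit <- time_limit_s
  res <- be$sp$milp(c = obj, constraints = cons,
                    integrality = be$np$array(as.integer(integrality)),
                    bounds = be$sp$Bounds(lb, ub),
                    options = reticulate::dict(opts))
  status <- switch(as.character(res$status),
                   "0" = "optimal", "1" = "time_limit", "2" = "infeasible",
                   "3" = "unbounded", "failed")
  list(status = status,
       x = if (status == "optimal") as.numeric(res$x) else NULL,
       fun = if (status == "optimal") as.numeric(res$fun) else NA_real_)
}
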