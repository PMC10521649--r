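#' Read a stoichiometric model from disk
#'
#' Three dialects are supported: the package's own fixture JSON schema
#' (`metabolites[]` with optional elemental tallies, `reactions[]` with
#' stoichiometry maps, `reversible` flags and `delta_g_kJ_mol`), BiGG-style
#' JSON (reversibility derived from `lower_bound < 0`), and SBML Level 3
#' with FBC flux bounds. Boundary/exchange reactions of genome-scale inputs
#' (prefixes `EX_`, `DM_`, `SK_`, `BIOMASS`) are dropped by default so that
#' the network is internally balanced.
#'
#' @param path File path.
#' @param format One of `"fixture_json"`, `"bigg_json"`, `"sbml"`.
#' @param keep_boundary Character vector of boundary reaction ids to retain.
#' @param check_elements Passed to [metabolic_network()].
#' @return A `metabolic_network`.
#' @export
read_model <- function(path, format = c("fixture_json", "bigg_json", "sbml"),
                       keep_boundary = character(), check_elements = c("C", "N", "P")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  switch(format,
    fixture_json = read_fixture_json(path, check_elements),
    bigg_json = read_bigg_json(path, keep_boundary),
    sbml = read_sbml(path, keep_boundary))
}

read_fixture_json <- function(path, check_elements = c("C", "N", "P")) {
  doc <- jsonlite::read_json(path)
  mets <- lapply(doc$metabolites, function(m)
    metabolite(m$id, name = if (!is.null(m$name)) m$name else m$id,
               elements = if (!is.null(m$elements)) unlist(m$elements),
               thermo_exempt = isTRUE(m$thermo_exempt)))
  rxns <- lapply(doc$reactions, function(r)
    reaction(r$id, stoichiometry = unlist(r$stoichiometry),
             reversible = isTRUE(r$reversible),
             delta_g = if (!is.null(r$delta_g_kJ_mol)) r$delta_g_kJ_mol else NA_real_,
             tags = if (!is.null(r$tags)) unlist(r$tags) else character()))
  metabolic_network(mets, rxns, check_elements = check_elements)
}

#' Write a network in the fixture JSON schema
#'
#' Round-trips exactly with [read_model()] on ids, stoichiometries,
#' reversibilities and standard Gibbs energies.
#'
#' @param network A `metabolic_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fixture_json <- function(network, path) {
  mets <- lapply(network$metabolites, function(m) {
    out <- list(id = m$id, name = m$name)
    if (!is.null(m$elements)) out$elements <- as.list(m$elements)
    if (isTRUE(m$thermo_exempt)) out$thermo_exempt <- TRUE
    out
  })
  rxns <- lapply(network$reactions, function(r) {
    out <- list(id = r$id, stoichiometry = as.list(r$stoichiometry),
                reversible = r$reversible)
    if (!is.na(r$delta_g)) out$delta_g_kJ_mol <- r$delta_g
    if (length(r$tags)) out$tags <- as.list(r$tags)
    out
  })
  jsonlite::write_json(list(metabolites = unname(mets), reactions = unname(rxns)),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

read_bigg_json <- function(path, keep_boundary = character()) {
  doc <- jsonlite::read_json(path)
  mets <- lapply(doc$metabolites, function(m)
    metabolite(m$id, name = if (!is.null(m$name)) m$name else m$id))
  rxns <- list()
  for (r in doc$reactions) {
    if (is_boundary_id(r$id) && !(r$id %in% keep_boundary)) next
    lb <- if (!is.null(r$lower_bound)) r$lower_bound else -1000
    st <- unlist(r$metabolites)
    rxns[[length(rxns) + 1L]] <-
      reaction(r$id, stoichiometry = st, reversible = lb < 0,
               delta_g = if (!is.null(r$delta_g_kJ_mol)) r$delta_g_kJ_mol else NA_real_)
  }
  metabolic_network(mets, rxns, check_elements = NULL)
}

is_boundary_id <- function(id) {
  grepl("^(EX_|DM_|SK_|BIOMASS)", id)
}

read_sbml <- function(path, keep_boundary = character()) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns(doc)
  params <- xml2::xml_find_all(doc, ".//d1:listOfParameters/d1:parameter", ns)
  pvals <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                           xml2::xml_attr(params, "id"))
  sp <- xml2::xml_find_all(doc, ".//d1:listOfSpecies/d1:species", ns)
  mets <- lapply(sp, function(s)
    metabolite(xml2::xml_attr(s, "id"),
               name = xml2::xml_attr(s, "name") %||% xml2::xml_attr(s, "id")))
  rx <- xml2::xml_find_all(doc, ".//d1:listOfReactions/d1:reaction", ns)
  rxns <- list()
  for (r in rx) {
    id <- xml2::xml_attr(r, "id")
    if (is_boundary_id(id) && !(id %in% keep_boundary)) next
    refs <- function(tag, sign) {
      nodes <- xml2::xml_find_all(r, paste0("./d1:", tag, "/d1:speciesReference"), ns)
      if (!length(nodes)) return(numeric())
      coef <- as.numeric(xml2::xml_attr(nodes, "stoichiometry"))
      coef[is.na(coef)] <- 1
      stats::setNames(sign * coef, xml2::xml_attr(nodes, "species"))
    }
    st <- c(refs("listOfReactants", -1), refs("listOfProducts", +1))
    st <- tapply(st, names(st), sum)
    st <- stats::setNames(as.numeric(st), names(st))
    st <- st[st != 0]
    lb_ref <- xml2::xml_attr(r, "lowerFluxBound")
    lb <- if (!is.na(lb_ref) && lb_ref %in% names(pvals)) pvals[[lb_ref]] else {
      rev_attr <- xml2::xml_attr(r, "reversible")
      if (identical(rev_attr, "true")) -1000 else 0
    }
    rxns[[length(rxns) + 1L]] <- reaction(id, st, reversible = lb < 0)
  }
  metabolic_network(mets, rxns, check_elements = NULL)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

#' Apply configured model alterations
#'
#' Alterations are applied in listed order. Each entry is a list with an
#' `op` field: `remove_reaction(id)`, `add_reaction(record)`,
#' `set_reversibility(id, reversible)`, `set_delta_g(id, value)`.
#'
#' @param network A `metabolic_network`.
#' @param alterations List of alteration entries (possibly empty).
#' @return The altered network.
#' @export
apply_alterations <- function(network, alterations = list()) {
  for (alt in alterations) {
    op <- alt$op
    if (is.null(op)) stop("alteration without 'op' field", call. = FALSE)
    if (op != "add_reaction" && is.null(network$reactions[[alt$id]]))
      stop("alteration references unknown reaction '", alt$id, "'", call. = FALSE)
    network <- switch(op,
      remove_reaction = {
        network$reactions[[alt$id]] <- NULL
        network
      },
      add_reaction = {
        rec <- alt$reaction
        if (!inherits(rec, "tp_reaction"))
          rec <- reaction(rec$id, unlist(rec$stoichiometry),
                          reversible = isTRUE(rec$reversible),
                          delta_g = rec$delta_g_kJ_mol %||% NA_real_)
        metabolic_network(network$metabolites,
                          c(network$reactions, list(rec)),
                          check_elements = NULL)
      },
      set_reversibility = {
        network$reactions[[alt$id]]$reversible <- isTRUE(alt$reversible)
        network
      },
      set_delta_g = {
        network$reactions[[alt$id]]$delta_g <- as.numeric(alt$value)
        network
      },
      stop("unknown alteration op '", op, "'", call. = FALSE))
  }
  network
}

#' Specify the injected net-conversion (objective) reaction
#'
#' The pathway search balances `source + n ADP + n Pi -> sink + n ATP`;
#' its rate is fixed at -1 so the rest of the network must supply the
#' conversion at unit rate.
#'
#' @param source,sink Metabolite ids (must differ).
#' @param atp_yield Signed integer n; for negative n the cofactor terms
#'   change sides.
#' @param cofactors Named character vector resolving the `atp`, `adp`
#'   and `pi` roles to metabolite ids.
#' @return A list of class `"objective_spec"`.
#' @export
objective_spec <- function(source = "glycerol", sink = "pyruvate", atp_yield = 0L,
                           cofactors = c(atp = "atp", adp = "adp", pi = "pi")) {
  if (identical(source, sink)) stop("source and sink must differ", call. = FALSE)
  stopifnot(atp_yield == round(atp_yield))
  structure(list(source = source, sink = sink, atp_yield = as.integer(atp_yield),
                 cofactors = cofactors),
            class = "objective_spec")
}

#' Inject the objective reaction into a network
#'
#' @param network A `metabolic_network` without an objective reaction.
#' @param spec An [objective_spec()].
#' @param id Reaction id to use for the injected reaction.
#' @return The network with one additional irreversible reaction flagged
#'   as objective.
#' @export
add_objective_reaction <- function(network, spec, id = "OBJ") {
  if (any(vapply(network$reactions, function(r) isTRUE(r$objective), logical(1))))
    stop("objective already injected", call. = FALSE)
  met_ids <- metabolite_ids(network)
  need <- c(spec$source, spec$sink)
  n <- spec$atp_yield
  st <- c(-1, +1)
  names(st) <- c(spec$source, spec$sink)
  if (n != 0L) {
    need <- c(need, unname(spec$cofactors))
    st[spec$cofactors[["adp"]]] <- -n
    st[spec$cofactors[["pi"]]] <- -n
    st[spec$cofactors[["atp"]]] <- +n
  }
  missing <- setdiff(need, met_ids)
  if (length(missing))
    stop("objective spec metabolites missing from network: ",
         paste(missing, collapse = ", "), call. = FALSE)
  obj <- reaction(id, st, reversible = FALSE, tags = "objective", objective = TRUE)
  network$reactions[[id]] <- obj
  network$objective_spec <- spec
  network
}

#' Split reversible reactions into unidirectional pairs
#'
#' Every reversible non-objective reaction becomes a forward and a backward
#' directed reaction (negated stoichiometry and Gibbs energy); irreversible
#' reactions keep a single forward copy unless `split_irreversible = TRUE`.
#' All directed rates are bounded to `[0, beta]`. The objective reaction is
#' carried separately: its rate is fixed at -1 downstream, it gets no
#' indicator and no flux cap.
#'
#' @param network A `metabolic_network` with an injected objective reaction.
#' @param beta Positive flux cap for every directed reaction.
#' @param split_irreversible Also create backward copies of irreversible
#'   reactions (a literal reading of splitting "all" reactions).
#' @param require_delta_g Error when a non-objective reaction lacks a
#'   standard Gibbs energy; set `FALSE` for thermodynamics-free runs.
#' @param thermo_unconstrained Ids of reactions exempted from the
#'   driving-force constraint (their directed copies carry `g0 = NA`).
#' @param temperature_K Temperature used to convert kJ/mol to RT units.
#' @return An object of class `"directed_network"`.
#' @export
split_reactions <- function(network, beta = 10, split_irreversible = FALSE,
                            require_delta_g = TRUE,
                            thermo_unconstrained = character(),
                            temperature_K = 298.15) {
  if (beta <= 0) stop("beta must be positive", call. = FALSE)
  obj <- Filter(function(r) isTRUE(r$objective), network$reactions)
  if (!length(obj)) stop("no objective reaction injected", call. = FALSE)
  obj <- obj[[1]]
  directed <- list()
  pairing <- list()
  for (r in network$reactions) {
    if (isTRUE(r$objective)) next
    exempted <- r$id %in% thermo_unconstrained
    if (require_delta_g && is.na(r$delta_g) && !exempted)
      stop("reaction '", r$id, "' lacks a standard Gibbs energy; ",
           "list it in 'thermo_unconstrained' or supply delta_g", call. = FALSE)
    g0 <- if (exempted || is.na(r$delta_g)) NA_real_
          else gibbs_to_rt(r$delta_g, temperature_K)
    fwd_id <- paste0(r$id, "_fwd")
    directed[[fwd_id]] <- list(id = fwd_id, parent = r$id, direction = "fwd",
                               stoich = r$stoichiometry, g0 = g0)
    if (r$reversible || split_irreversible) {
      bwd_id <- paste0(r$id, "_bwd")
      directed[[bwd_id]] <- list(id = bwd_id, parent = r$id, direction = "bwd",
                                 stoich = -r$stoichiometry, g0 = -g0)
      pairing[[r$id]] <- c(fwd = fwd_id, bwd = bwd_id)
    } else {
      pairing[[r$id]] <- c(fwd = fwd_id)
    }
  }
  structure(list(reactions = directed, pairing = pairing,
                 objective = list(id = obj$id, stoich = obj$stoichiometry),
                 metabolites = network$metabolites, beta = beta,
                 temperature_K = temperature_K),
            class = "directed_network")
}

#' @export
print.directed_network <- function(x, ...) {
  cat("Directed network: ", length(x$reactions), " directed reactions from ",
      length(x$pairing), " parents; beta = ", x$beta, "\n", sep = "")
  cat("Objective: ", x$objective$id, " [",
      format_stoichiometry(x$objective$stoich), "], rate fixed at -1\n", sep = "")
  invisible(x)
}

#' Dump a directed network as TSV (debugging aid)
#'
#' @param directed A `directed_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_directed_tsv <- function(directed, path) {
  rows <- lapply(directed$reactions, function(d) data.frame(
    directed_id = d$id, parent_id = d$parent, direction = d$direction,
    g0_RT = d$g0,
    stoichiometry = paste(sprintf("%s:%g", names(d$stoich), d$stoich),
                          collapse = ",")))
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
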