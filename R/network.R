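#' Construct a metabolite record
#'
#' Metabolites are the rows of the stoichiometric matrix and, unless flagged
#' `thermo_exempt`, carry a log-concentration variable in thermodynamically
#' constrained searches. Water and protons are conventionally exempt (their
#' activities are absorbed into transformed standard Gibbs energies).
#'
#' @param id Short unique identifier.
#' @param name Free-text name; defaults to `id`.
#' @param elements Optional named numeric vector of elemental counts
#'   (e.g. `c(C = 3, N = 0, P = 1)`). Used for balance checking.
#' @param thermo_exempt Logical; exclude this species from the
#'   concentration term of the driving-force constraints.
#' @return A list of class `"tp_metabolite"`.
#' @export
metabolite <- function(id, name = id, elements = NULL, thermo_exempt = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!is.null(elements)) {
    if (is.null(names(elements)) || any(!nzchar(names(elements))))
      stop("'elements' must be a named numeric vector", call. = FALSE)
    if (any(elements < 0) || any(elements != round(elements)))
      stop("elemental counts must be non-negative integers", call. = FALSE)
  }
  structure(list(id = id, name = name, elements = elements,
                 thermo_exempt = isTRUE(thermo_exempt)),
            class = "tp_metabolite")
}

#' Construct a reaction record
#'
#' @param id Short unique identifier.
#' @param stoichiometry Named numeric vector, metabolite id -> signed
#'   coefficient (negative = consumed). Must be non-empty with no zeros.
#' @param reversible Logical.
#' @param delta_g Transformed standard reaction Gibbs energy in kJ/mol
#'   (`NA` allowed; required for thermodynamically constrained runs).
#' @param tags Character vector of free-form labels.
#' @param objective Logical; marks the injected net-conversion reaction.
#' @return A list of class `"tp_reaction"`.
#' @export
reaction <- function(id, stoichiometry, reversible = FALSE,
                     delta_g = NA_real_, tags = character(), objective = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (length(stoichiometry) == 0L)
    stop("reaction '", id, "': stoichiometry is empty", call. = FALSE)
  if (is.null(names(stoichiometry)) || any(!nzchar(names(stoichiometry))))
    stop("reaction '", id, "': stoichiometry must be a named vector", call. = FALSE)
  if (anyDuplicated(names(stoichiometry)))
    stop("reaction '", id, "': duplicated metabolite in stoichiometry", call. = FALSE)
  if (any(stoichiometry == 0))
    stop("reaction '", id, "': zero stoichiometric coefficient", call. = FALSE)
  structure(list(id = id, stoichiometry = stoichiometry,
                 reversible = isTRUE(reversible), delta_g = as.numeric(delta_g),
                 tags = as.character(tags), objective = isTRUE(objective)),
            class = "tp_reaction")
}

#' Assemble a metabolic network
#'
#' Validates that reaction stoichiometries only reference declared
#' metabolites, that ids are unique, and (when elemental tallies are present
#' on every participant of a reaction) that carbon, nitrogen and phosphorus
#' balance exactly.
#'
#' @param metabolites List of [metabolite()] records.
#' @param reactions List of [reaction()] records.
#' @param check_elements Elements required to balance when tallies are
#'   available; set `NULL` to skip.
#' @return An object of class `"metabolic_network"`.
#' @export
metabolic_network <- function(metabolites, reactions,
                              check_elements = c("C", "N", "P")) {
  met_ids <- vapply(metabolites, `[[`, character(1), "id")
  if (anyDuplicated(met_ids))
    stop("duplicate metabolite ids: ",
         paste(unique(met_ids[duplicated(met_ids)]), collapse = ", "),
         call. = FALSE)
  rxn_ids <- vapply(reactions, `[[`, character(1), "id")
  if (anyDuplicated(rxn_ids))
    stop("duplicate reaction ids: ",
         paste(unique(rxn_ids[duplicated(rxn_ids)]), collapse = ", "),
         call. = FALSE)
  names(metabolites) <- met_ids
  names(reactions) <- rxn_ids
  for (r in reactions) {
    missing <- setdiff(names(r$stoichiometry), met_ids)
    if (length(missing))
      stop("reaction '", r$id, "' references undeclared metabolite: ",
           paste(missing, collapse = ", "), call. = FALSE)
  }
  net <- structure(list(metabolites = metabolites, reactions = reactions),
                   class = "metabolic_network")
  if (!is.null(check_elements)) {
    bad <- elemental_imbalance(net, check_elements)
    if (nrow(bad))
      stop("elementally unbalanced reaction(s): ",
           paste(sprintf("%s (%s: %+g)", bad$reaction, bad$element, bad$imbalance),
                 collapse = "; "), call. = FALSE)
  }
  net
}

#' Elemental balance residuals of a network
#'
#' A reaction is checked only when every participant carries an elemental
#' tally; reactions with any untallied participant are skipped.
#'
#' @param network A `metabolic_network`.
#' @param elements Elements to check.
#' @return A data frame with columns `reaction`, `element`, `imbalance`
#'   containing only the non-zero residuals.
#' @export
elemental_imbalance <- function(network, elements = c("C", "N", "P")) {
  out <- list()
  for (r in network$reactions) {
    parts <- network$metabolites[names(r$stoichiometry)]
    tallies <- lapply(parts, `[[`, "elements")
    if (any(vapply(tallies, is.null, logical(1)))) next
    for (el in elements) {
      counts <- vapply(tallies, function(e) if (el %in% names(e)) e[[el]] else 0,
                       numeric(1))
      res <- sum(r$stoichiometry * counts)
      if (abs(res) > 1e-9)
        out[[length(out) + 1L]] <- data.frame(reaction = r$id, element = el,
                                              imbalance = res)
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(reaction = character(), element = character(),
                  imbalance = numeric())
}

#' Stoichiometric matrix of a network
#'
#' @param network A `metabolic_network` or `directed_network`.
#' @param include_objective Keep the injected objective reaction column?
#' @return A dense metabolite-by-reaction matrix with signed coefficients.
#' @export
stoichiometric_matrix <- function(network, include_objective = TRUE) {
  rxns <- network$reactions
  if (!include_objective)
    rxns <- Filter(function(r) !isTRUE(r$objective), rxns)
  met_ids <- metabolite_ids(network)
  S <- matrix(0, nrow = length(met_ids), ncol = length(rxns),
              dimnames = list(met_ids, vapply(rxns, `[[`, character(1), "id")))
  for (r in rxns) {
    st <- if (!is.null(r$stoichiometry)) r$stoichiometry else r$stoich
    S[names(st), r$id] <- st
  }
  S
}

metabolite_ids <- function(network) {
  vapply(network$metabolites, `[[`, character(1), "id")
}

reaction_ids <- function(network) {
  vapply(network$reactions, `[[`, character(1), "id")
}

exempt_ids <- function(network) {
  ids <- metabolite_ids(network)
  ids[vapply(network$metabolites, function(m) isTRUE(m$thermo_exempt), logical(1))]
}

#' @export
print.metabolic_network <- function(x, ...) {
  n_rev <- sum(vapply(x$reactions, `[[`, logical(1), "reversible"))
  obj <- Filter(function(r) isTRUE(r$objective), x$reactions)
  cat("Metabolic network: ", length(x$metabolites), " metabolites, ",
      length(x$reactions), " reactions (", n_rev, " reversible)\n", sep = "")
  if (length(obj))
    cat("Objective reaction: ", obj[[1]]$id, " [",
        format_stoichiometry(obj[[1]]$stoichiometry), "]\n", sep = "")
  invisible(x)
}

#' @export
summary.metabolic_network <- function(object, ...) {
  has_g <- sum(!is.na(vapply(object$reactions, `[[`, numeric(1), "delta_g")))
  print(object)
  cat(has_g, "reactions carry standard Gibbs energies\n")
  invisible(object)
}

format_stoichiometry <- function(st) {
  lhs <- st[st < 0]; rhs <- st[st > 0]
  fmt <- function(v, sign) paste(
    ifelse(abs(v) == 1, names(v), paste0(abs(v), " ", names(v))), collapse = " + ")
  paste(fmt(lhs), "->", fmt(rhs))
}
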