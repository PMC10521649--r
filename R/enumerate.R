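#' Enumerate minimal pathways for one ATP yield
#'
#' Repeats solve -> record -> cut until the problem becomes infeasible,
#' the solution cap is reached, or the time limit hits. Each recorded
#' solution is independently re-verified with [verify_solution()]; a
#' solution failing verification is rejected with a typed status.
#'
#' @param directed A `directed_network` whose objective reaction was
#'   injected with this ATP yield.
#' @param thermo A [thermo_params()] object.
#' @param config An [enumeration_config()].
#' @param atp_yield Integer yield recorded on the solutions.
#' @param verbose Log one line per iteration to standard error.
#' @return An object of class `"solution_set"` with fields `atp_yield`,
#'   `solutions`, `status` (`"cap_reached"`, `"exhausted"`, `"time_limit"`
#'   or `"verification_failed"`) and `cuts_applied`.
#' @export
enumerate_pathways <- function(directed, thermo, config = enumeration_config(),
                               atp_yield = NA_integer_, verbose = FALSE) {
  attr(directed, "atp_yield") <- atp_yield
  problem <- build_milp(directed, thermo, config)
  solutions <- list()
  status <- "exhausted"
  repeat {
    t0 <- proc.time()[["elapsed"]]
    sol <- solve_min_pathway(problem, config)
    if (inherits(sol, "milp_status")) {
      status <- if (sol$status == "infeasible") "exhausted" else sol$status
      break
    }
    rep_ <- verify_solution(directed, thermo, sol, tolerance = config$tolerance)
    if (!rep_$passed) {
      status <- "verification_failed"
      break
    }
    solutions[[length(solutions) + 1L]] <- sol
    if (verbose)
      message(sprintf("yield %s iteration %d: |active| = %d (%.2fs)",
                      format(atp_yield), length(solutions), sol$cardinality,
                      proc.time()[["elapsed"]] - t0))
    if (length(solutions) >= config$max_solutions) {
      status <- "cap_reached"
      break
    }
    problem <- add_integer_cut(problem, sol, config$cut_radius)
  }
  structure(list(atp_yield = atp_yield, solutions = solutions, status = status,
                 cuts_applied = length(problem$cuts),
                 directed = directed, thermo = thermo),
            class = "solution_set")
}

#' Scan ATP yields
#'
#' For each yield `n`, injects the objective reaction
#' `source + n ADP + n Pi -> sink + n ATP`, splits the network into
#' unidirectional reactions, and enumerates minimal pathways with an
#' independent cut pool per yield.
#'
#' @param network A `metabolic_network` without an objective reaction.
#' @param config An [enumeration_config()]; its `atp_yields` field defines
#'   the scan unless `atp_yields` is given.
#' @param objective An [objective_spec()] template (its `atp_yield` field
#'   is overwritten per scan point).
#' @param overrides Concentration overrides for
#'   [build_concentration_bounds()]; defaults to
#'   [default_metabolite_ranges()] restricted to metabolites present.
#' @param atp_yields Optional integer vector overriding the config scan set.
#' @param verbose Log per-iteration lines to standard error.
#' @return An object of class `"pathway_scan"`: a list of `solution_set`s
#'   keyed by yield, with the network attached.
#' @export
scan_atp_yields <- function(network, config = enumeration_config(),
                            objective = objective_spec(),
                            overrides = NULL, atp_yields = NULL,
                            verbose = FALSE) {
  if (is.null(atp_yields)) atp_yields <- config$atp_yields
  if (is.null(overrides)) {
    overrides <- default_metabolite_ranges()
    overrides <- overrides[overrides$id %in% metabolite_ids(network), ]
  }
  sets <- list()
  for (n in atp_yields) {
    spec_n <- objective
    spec_n$atp_yield <- as.integer(n)
    with_obj <- add_objective_reaction(network, spec_n)
    directed <- split_reactions(with_obj, beta = config$beta)
    bounds <- build_concentration_bounds(directed, overrides)
    thermo <- thermo_params(directed, bounds)
    sets[[as.character(n)]] <-
      enumerate_pathways(directed, thermo, config, atp_yield = as.integer(n),
                         verbose = verbose)
  }
  structure(list(solution_sets = sets, network = network, config = config,
                 objective = objective, overrides = overrides),
            class = "pathway_scan")
}

#' @export
print.solution_set <- function(x, ...) {
  cat("Solution set (ATP yield ", format(x$atp_yield), "): ",
      length(x$solutions), " solution(s), status '", x$status, "', ",
      x$cuts_applied, " cuts\n", sep = "")
  for (s in x$solutions)
    cat("  |active| = ", s$cardinality, ": ",
        paste(sort(sub("_(fwd|bwd)$", "", s$active_set)), collapse = " "),
        "\n", sep = "")
  invisible(x)
}

#' @export
print.pathway_scan <- function(x, ...) {
  cat("Pathway scan over ATP yields {",
      paste(names(x$solution_sets), collapse = ", "), "}\n", sep = "")
  for (s in x$solution_sets)
    cat("  n = ", format(s$atp_yield), ": ", length(s$solutions),
        " solution(s), ", s$status, "\n", sep = "")
  invisible(x)
}

#' @export
summary.pathway_scan <- function(object, markers = strategy_markers(), ...) {
  print(object)
  labs <- sort(unique(unlist(lapply(all_solutions(object), classify_strategy,
                                    markers = markers))))
  cat("Strategies found: ", if (length(labs)) paste(labs, collapse = ", ")
      else "(none)", "\n", sep = "")
  invisible(object)
}

#' @export
as.data.frame.pathway_scan <- function(x, ...) {
  rows <- list()
  for (set in x$solution_sets) {
    for (k in seq_along(set$solutions)) {
      s <- set$solutions[[k]]
      rows[[length(rows) + 1L]] <- data.frame(
        atp_yield = set$atp_yield, solution = k, cardinality = s$cardinality,
        reactions = paste(sort(s$active_set), collapse = ";"))
    }
  }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(atp_yield = integer(), solution = integer(),
                  cardinality = integer(), reactions = character())
}

all_solutions <- function(scan) {
  if (inherits(scan, "solution_set")) return(scan$solutions)
  if (inherits(scan, "pathway_scan"))
    return(unlist(lapply(scan$solution_sets, `[[`, "solutions"),
                  recursive = FALSE))
  stop("expected a pathway_scan or solution_set", call. = FALSE)
}
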