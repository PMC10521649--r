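#' Independently verify a pathway solution
#'
#' Re-checks, with plain arithmetic and no solver, that a solution
#' satisfies steady-state mass balance (with the objective rate at -1),
#' the flux caps, the coupling between flux support and the indicator
#' set, and the second law (driving force >= 0) for every active reaction
#' at the returned log-concentrations.
#'
#' @param directed A `directed_network`.
#' @param thermo A [thermo_params()] object.
#' @param solution A `pathway_solution`.
#' @param tolerance Numerical tolerance.
#' @return A list of class `"verification_report"` with the maximal mass
#'   balance residual, violation counts, the list of thermodynamic
#'   violations, and a `passed` flag.
#' @export
verify_solution <- function(directed, thermo, solution, tolerance = 1e-6) {
  ids <- names(directed$reactions)
  unknown <- setdiff(c(solution$active_set, names(solution$fluxes)), ids)
  if (length(unknown))
    stop("solution references unknown directed reaction: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  v <- stats::setNames(rep(0, length(ids)), ids)
  v[names(solution$fluxes)] <- solution$fluxes

  met_ids <- metabolite_ids(directed)
  resid <- stats::setNames(rep(0, length(met_ids)), met_ids)
  for (d in directed$reactions)
    resid[names(d$stoich)] <- resid[names(d$stoich)] + d$stoich * v[[d$id]]
  ob <- directed$objective$stoich
  resid[names(ob)] <- resid[names(ob)] - ob      # v_obj = -1
  mass_resid <- max(abs(resid))

  flux_viol <- sum(v < -tolerance | v > directed$beta + tolerance)
  support <- ids[v > tolerance]
  indicator_viol <- length(setdiff(support, solution$active_set))

  thermo_viol <- list()
  for (id in solution$active_set) {
    d <- directed$reactions[[id]]
    if (is.na(thermo$g0[[id]])) next
    df <- driving_force(d$stoich, thermo$g0[[id]], solution$ln_concentrations,
                        exempt = thermo$exempt)
    if (df < -tolerance)
      thermo_viol[[length(thermo_viol) + 1L]] <- list(id = id, delta_g_RT = -df)
  }
  passed <- mass_resid <= max(tolerance, 1e-6) && flux_viol == 0L &&
    indicator_viol == 0L && length(thermo_viol) == 0L
  structure(list(mass_balance_max_residual = mass_resid,
                 flux_bound_violations = flux_viol,
                 indicator_violations = indicator_viol,
                 thermo_violations = thermo_viol, passed = passed),
            class = "verification_report")
}

#' @export
print.verification_report <- function(x, ...) {
  cat("Verification: ", if (x$passed) "PASSED" else "FAILED",
      " (max |Sv| = ", format(x$mass_balance_max_residual, digits = 3),
      ", flux violations ", x$flux_bound_violations,
      ", indicator violations ", x$indicator_violations,
      ", thermodynamic violations ", length(x$thermo_violations), ")\n",
      sep = "")
  invisible(x)
}

#' Snap a numeric vector to nearby small rationals
#'
#' Continued-fraction rounding used so stoichiometric flux sums (e.g. net
#' ATP per pyruvate) are reported as exact rationals rather than
#' solver-precision floats.
#'
#' @param x Numeric vector.
#' @param max_denominator Largest admissible denominator.
#' @param tol Acceptance tolerance for the snap.
#' @return Numeric vector with near-rational entries replaced exactly.
#' @export
rationalise <- function(x, max_denominator = 1000L, tol = 1e-6) {
  snap1 <- function(v) {
    if (!is.finite(v)) return(v)
    for (q in seq_len(max_denominator)) {
      p <- round(v * q)
      if (abs(v - p / q) < tol) return(p / q)
    }
    v
  }
  vapply(x, snap1, numeric(1))
}

#' Net ATP yield of a solution per unit sink production
#'
#' Sums `v_i * (ATP coefficient of reaction i)` over all non-objective
#' reactions and normalises by the net sink production rate (1 by
#' construction). ATP accounting is by ATP coefficients: a reaction
#' converting ATP to AMP counts as -1 ATP, with adenylate kinase closing
#' the AMP balance. For any valid solution the value equals the injected
#' yield n (cross-checked by the mass balance of ATP itself).
#'
#' @param directed A `directed_network`.
#' @param solution A `pathway_solution`.
#' @param atp,sink Metabolite ids for ATP and the sink.
#' @return A (snapped) rational scalar.
#' @export
net_atp_yield <- function(directed, solution, atp = "atp",
                          sink = names(directed$objective$stoich)[
                            directed$objective$stoich > 0][1]) {
  if (!atp %in% metabolite_ids(directed))
    stop("ATP id '", atp, "' not in network", call. = FALSE)
  total <- 0; sink_prod <- 0
  for (id in names(solution$fluxes)) {
    d <- directed$reactions[[id]]
    if (is.null(d)) next
    vi <- solution$fluxes[[id]]
    if (atp %in% names(d$stoich)) total <- total + vi * d$stoich[[atp]]
    if (sink %in% names(d$stoich)) sink_prod <- sink_prod + vi * d$stoich[[sink]]
  }
  if (abs(sink_prod) < 1e-9) stop("solution produces no sink", call. = FALSE)
  rationalise(total / sink_prod)
}

#' Default strategy marker sets
#'
#' Marker reactions of the four broad glycerol-to-pyruvate strategies:
#' lower EMP glycolysis (phosphoglycerate mutase, enolase, pyruvate
#' kinase), the Entner-Doudoroff pathway (KDPG aldolase), the
#' methylglyoxal bypass (methylglyoxal synthase), and the serine shunt
#' (serine deaminase together with the three serine biosynthesis steps).
#' A label applies only when every listed reaction is active.
#'
#' @return Named list of character vectors of reaction ids.
#' @export
strategy_markers <- function() {
  list(EMP = c("PGM", "ENO", "PYK"),
       ED = "EDA",
       methylglyoxal = "MGSA",
       serine_shunt = c("SDAA", "SERA", "SERC", "SERB"))
}

active_parents <- function(solution) {
  unique(sub("_(fwd|bwd)$", "", solution$active_set))
}

#' Classify a solution into broad strategies
#'
#' A strategy label is assigned when all of its marker reactions are in
#' the active set (in either direction). Solutions may combine several
#' strategies; an empty result means unclassified.
#'
#' @param solution A `pathway_solution`.
#' @param markers Named list of marker reaction-id vectors.
#' @return Character vector of strategy labels (possibly empty).
#' @export
classify_strategy <- function(solution, markers = strategy_markers()) {
  parents <- active_parents(solution)
  names(Filter(function(req) all(req %in% parents), markers))
}

#' Metabolites treated as cofactors during route extraction
#'
#' Path finding between carbon intermediates must not shortcut through
#' shared cofactor pools; these metabolite nodes are removed from the
#' active-subnetwork graph. Glutathione is listed as a cofactor, yet the
#' methylglyoxal-glutathione ligation still anchors its segment because
#' the path enters through methylglyoxal, not through glutathione.
#'
#' @return Character vector of metabolite ids.
#' @export
default_cofactors <- function() {
  c("atp", "adp", "amp", "pi", "nad", "nadh", "nadp", "nadph",
    "q", "qh2", "gsh", "glutamate", "akg", "nh3", "coa")
}

#' Extract the main-carbon route segment between two metabolites
#'
#' Builds the bipartite metabolite-reaction graph of the active
#' subnetwork (cofactor nodes removed), finds the shortest directed path
#' from `from` to `to`, and returns the reaction sequence along it.
#'
#' @param directed A `directed_network`.
#' @param solution A `pathway_solution`.
#' @param from,to Metabolite ids.
#' @param via Optional waypoint metabolite id: the segment is then the
#'   concatenation of the shortest `from -> via` and `via -> to` paths.
#'   Useful when a solution combines several strategies and the plain
#'   shortest path would follow the competing route (e.g. the serine
#'   shunt is, by definition, the 3PG -> pyruvate route through serine).
#' @param cofactors Metabolite ids excluded as path nodes.
#' @return Character vector of parent reaction ids in path order, or a
#'   list of class `"route_status"` with `status = "no_path"` when the
#'   two metabolites are not connected in the active subnetwork.
#' @export
route_segment <- function(directed, solution, from, to, via = NULL,
                          cofactors = default_cofactors()) {
  if (!is.null(via)) {
    first <- route_segment(directed, solution, from, via, cofactors = cofactors)
    second <- route_segment(directed, solution, via, to, cofactors = cofactors)
    if (inherits(first, "route_status") || inherits(second, "route_status"))
      return(structure(list(status = "no_path"), class = "route_status"))
    return(c(first, second))
  }
  edges <- character()
  for (id in solution$active_set) {
    d <- directed$reactions[[id]]
    if (is.null(d)) next
    rnode <- paste0("r:", id)
    for (met in names(d$stoich)) {
      if (met %in% cofactors) next
      if (d$stoich[[met]] < 0) edges <- c(edges, paste0("m:", met), rnode)
      else edges <- c(edges, rnode, paste0("m:", met))
    }
  }
  vf <- paste0("m:", from); vt <- paste0("m:", to)
  if (!length(edges) || !all(c(vf, vt) %in% edges))
    return(structure(list(status = "no_path"), class = "route_status"))
  g <- igraph::make_graph(edges, directed = TRUE)
  path <- suppressWarnings(
    igraph::shortest_paths(g, from = vf, to = vt, mode = "out"))$vpath[[1]]
  if (!length(path))
    return(structure(list(status = "no_path"), class = "route_status"))
  nodes <- igraph::V(g)$name[as.integer(path)]
  rxns <- sub("^r:", "", nodes[startsWith(nodes, "r:")])
  sub("_(fwd|bwd)$", "", rxns)
}

#' Count distinct route-segment variants across a scan
#'
#' Applies [route_segment()] to every enumerated solution whose active
#' subnetwork connects the two metabolites and counts distinct variants,
#' where two segments are distinct when their reaction-id sets differ
#' (cofactor-swapped segments therefore count separately).
#'
#' @param scan A `pathway_scan` or `solution_set`.
#' @param from,to Metabolite ids.
#' @param cofactors Passed to [route_segment()].
#' @return Integer count; the distinct segments are attached as the
#'   `"segments"` attribute.
#' @export
count_segment_variants <- function(scan, from, to,
                                   cofactors = default_cofactors()) {
  sets <- if (inherits(scan, "solution_set")) list(scan) else scan$solution_sets
  segs <- list()
  for (set in sets) {
    if (is.null(set$directed)) next
    for (s in set$solutions) {
      seg <- route_segment(set$directed, s, from, to, cofactors = cofactors)
      if (inherits(seg, "route_status")) next
      key <- paste(sort(unique(seg)), collapse = "|")
      segs[[key]] <- seg
    }
  }
  structure(length(segs), segments = unname(segs))
}

#' Count distinct strategies across a scan
#'
#' @param scan A `pathway_scan` or `solution_set`.
#' @param markers Named list of marker sets.
#' @return Integer count of distinct labels (unclassified excluded), with
#'   the labels attached as the `"labels"` attribute.
#' @export
count_strategies <- function(scan, markers = strategy_markers()) {
  labs <- sort(unique(unlist(lapply(all_solutions(scan), classify_strategy,
                                    markers = markers))))
  structure(length(labs), labels = labs)
}

#' Export enumerated solutions to disk
#'
#' Writes one JSON per solution set (yield, status, solutions with active
#' sets, fluxes, log-concentrations and cardinality), a flat solutions
#' TSV, and a per-solution annotation table (strategies, net ATP,
#' methylglyoxal and serine segment lengths).
#'
#' @param scan A `pathway_scan`.
#' @param out_dir Output directory (created if needed).
#' @param markers Strategy markers for the annotation table.
#' @return Character vector of files written, invisibly.
#' @export
export_solutions <- function(scan, out_dir, markers = strategy_markers()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  flat <- list(); annot <- list()
  for (set in scan$solution_sets) {
    payload <- list(
      atp_yield = set$atp_yield, status = set$status,
      solutions = lapply(set$solutions, function(s) list(
        active_set = as.list(sort(s$active_set)),
        fluxes = as.list(s$fluxes[s$fluxes > 1e-9]),
        ln_concentrations = as.list(s$ln_concentrations),
        cardinality = s$cardinality)))
    f <- file.path(out_dir, sprintf("solutions_n%+d.json", set$atp_yield))
    jsonlite::write_json(payload, f, auto_unbox = TRUE, digits = NA)
    files <- c(files, f)
    for (k in seq_along(set$solutions)) {
      s <- set$solutions[[k]]
      sid <- sprintf("n%+d_s%02d", set$atp_yield, k)
      flat[[sid]] <- data.frame(solution_id = sid, atp_yield = set$atp_yield,
                                cardinality = s$cardinality,
                                reaction_ids = paste(sort(s$active_set),
                                                     collapse = ";"))
      seg_len <- function(from, to, via = NULL) {
        seg <- route_segment(set$directed, s, from, to, via = via)
        if (inherits(seg, "route_status")) NA_integer_ else length(seg)
      }
      annot[[sid]] <- data.frame(
        solution_id = sid, atp_yield = set$atp_yield,
        cardinality = s$cardinality,
        strategies = paste(classify_strategy(s, markers), collapse = ","),
        net_atp = net_atp_yield(set$directed, s),
        mg_segment_len = seg_len("mgx", "pyruvate"),
        serine_segment_len = seg_len("3pg", "pyruvate", via = "serine"))
    }
  }
  for (nm in c("solutions", "annotations")) {
    tab <- do.call(rbind, if (nm == "solutions") flat else annot)
    f <- file.path(out_dir, paste0(nm, ".tsv"))
    utils::write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }
  invisible(files)
}
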