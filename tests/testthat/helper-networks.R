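# Small networks and cached fixture scans shared across test files.
# All built in code; the MILP scan of the curated fixture is memoised so
# several test files can reuse one solve.

RT_KJ <- 8.314462618e-3 * 298.15

# linear chain source -> ... -> sink, one metabolite per step
chain_network <- function(g0_rt = c(-1, -1), ids = NULL) {
  n <- length(g0_rt)
  mets <- paste0("m", seq_len(n + 1))
  if (is.null(ids)) ids <- paste0("R", seq_len(n))
  rxns <- lapply(seq_len(n), function(k)
    reaction(ids[k], stats::setNames(c(-1, 1), mets[c(k, k + 1)]),
             delta_g = g0_rt[k] * RT_KJ))
  metabolic_network(lapply(mets, metabolite), rxns, check_elements = NULL)
}

# two routes src -> mid -> snk that share the second step
shared_step_network <- function() {
  mets <- lapply(c("src", "mid", "snk"), metabolite)
  rxns <- list(
    reaction("R1", c(src = -1, mid = 1), delta_g = -2 * RT_KJ),
    reaction("R3", c(src = -1, mid = 1), delta_g = -2 * RT_KJ),
    reaction("R2", c(mid = -1, snk = 1), delta_g = -2 * RT_KJ))
  metabolic_network(mets, rxns, check_elements = NULL)
}

# objective + split + default-box thermo for a plain source -> sink search
searchable <- function(network, source, sink, beta = 10, atp_yield = 0L,
                       overrides = NULL) {
  with_obj <- add_objective_reaction(
    network, objective_spec(source = source, sink = sink,
                            atp_yield = atp_yield))
  directed <- split_reactions(with_obj, beta = beta)
  bounds <- build_concentration_bounds(directed, overrides)
  list(directed = directed, thermo = thermo_params(directed, bounds))
}

.scan_cache <- new.env(parent = emptyenv())

# fixture scan over ATP yields -1, 0, +1 (the desk-scale twin of the
# published search), computed once per test run
fixture_scan <- function() {
  if (is.null(.scan_cache$scan)) {
    net <- build_central_carbon_fixture()
    .scan_cache$scan <- scan_atp_yields(net, atp_yields = c(-1L, 0L, 1L))
  }
  .scan_cache$scan
}

solutions_with_label <- function(scan, label, markers = strategy_markers()) {
  keep <- list()
  for (set in scan$solution_sets) {
    for (s in set$solutions) {
      if (label %in% classify_strategy(s, markers))
        keep[[length(keep) + 1L]] <- list(set = set, solution = s)
    }
  }
  keep
}

indicator_vector <- function(solution, rxn_ids) {
  as.integer(rxn_ids %in% solution$active_set)
}
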