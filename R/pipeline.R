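#' Run the full bypass-search pipeline
#'
#' Executes read -> alter -> inject -> split -> scan -> verify -> classify
#' -> export and writes the solution-set JSONs, the flat and annotation
#' TSVs, and a run manifest (configuration echo, package version, seed,
#' per-yield status, output hashes) into `out_dir`.
#'
#' @param model A `metabolic_network`, or a path readable by
#'   [read_model()].
#' @param out_dir Output directory.
#' @param format Model format when `model` is a path.
#' @param alterations Alteration list for [apply_alterations()].
#' @param objective An [objective_spec()] template.
#' @param config An [enumeration_config()].
#' @param overrides Concentration overrides data frame, a TSV path, or
#'   `NULL` for the shipped defaults.
#' @param markers Strategy markers.
#' @param seed Integer seed recorded in the manifest (the search is
#'   deterministic; the seed matters only for stochastic model generators
#'   used upstream).
#' @param verbose Log per-iteration lines.
#' @return The `pathway_scan`, invisibly; side effect: files in `out_dir`.
#' @export
run_pipeline <- function(model, out_dir, format = "fixture_json",
                         alterations = list(), objective = objective_spec(),
                         config = enumeration_config(), overrides = NULL,
                         markers = strategy_markers(), seed = 1L,
                         verbose = FALSE) {
  set.seed(seed)
  network <- if (inherits(model, "metabolic_network")) model
             else read_model(model, format)
  network <- apply_alterations(network, alterations)
  if (is.character(overrides)) overrides <- read_concentration_overrides(overrides)
  scan <- scan_atp_yields(network, config = config, objective = objective,
                          overrides = overrides, verbose = verbose)
  files <- export_solutions(scan, out_dir, markers = markers)
  n_strat <- count_strategies(scan, markers)
  manifest <- list(
    package = "thermopath",
    version = as.character(utils::packageVersion("thermopath")),
    seed = seed,
    objective = list(source = objective$source, sink = objective$sink),
    config = unclass(config),
    atp_yields = config$atp_yields,
    status = lapply(scan$solution_sets, function(s)
      list(atp_yield = s$atp_yield, n_solutions = length(s$solutions),
           status = s$status)),
    n_strategies = as.integer(n_strat),
    strategies = attr(n_strat, "labels"),
    outputs = lapply(files, function(f)
      list(file = basename(f), md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(scan)
}
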