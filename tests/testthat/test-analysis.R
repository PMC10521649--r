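test_that("verification detects constructed violations", {
  parts <- searchable(chain_network(c(-1, -1)), "m1", "m3")
  sol <- solve_min_pathway(build_milp(parts$directed, parts$thermo,
                                      enumeration_config()))
  ok <- verify_solution(parts$directed, parts$thermo, sol)
  expect_true(ok$passed)

  perturbed <- sol
  perturbed$fluxes[["R1_fwd"]] <- perturbed$fluxes[["R1_fwd"]] + 0.1
  bad <- verify_solution(parts$directed, parts$thermo, perturbed)
  expect_false(bad$passed)
  expect_equal(bad$mass_balance_max_residual, 0.1, tolerance = 1e-9)

  # hand-built solution running an endergonic reaction at its x
  parts2 <- searchable(chain_network(c(2, -1)), "m1", "m3")
  x_flat <- stats::setNames(rep(log(1e-4), 3), paste0("m", 1:3))
  hand <- structure(list(
    active_set = c("R1_fwd", "R2_fwd"),
    fluxes = c(R1_fwd = 1, R2_fwd = 1),
    ln_concentrations = x_flat, cardinality = 2L), class = "pathway_solution")
  rep2 <- verify_solution(parts2$directed, parts2$thermo, hand)
  expect_false(rep2$passed)
  expect_identical(vapply(rep2$thermo_violations, `[[`, character(1), "id"),
                   "R1_fwd")
  expect_error(verify_solution(parts$directed, parts$thermo,
                               structure(list(active_set = "GHOST",
                                              fluxes = c(GHOST = 1)),
                                         class = "pathway_solution")),
               "unknown directed reaction")
})

test_that("net ATP per pyruvate is exact for the three named routes", {
  scan <- fixture_scan()
  serine <- solutions_with_label(scan, "serine_shunt")
  serine <- Filter(function(e) e$set$atp_yield == 0L, serine)
  expect_gt(length(serine), 0)
  expect_identical(net_atp_yield(serine[[1]]$set$directed,
                                 serine[[1]]$solution), 0)

  mg <- solutions_with_label(scan, "methylglyoxal")
  mg <- Filter(function(e) e$set$atp_yield == -1L &&
                 !"EDA" %in% sub("_(fwd|bwd)$", "", e$solution$active_set),
               mg)
  expect_gt(length(mg), 0)
  expect_identical(net_atp_yield(mg[[1]]$set$directed, mg[[1]]$solution), -1)

  emp <- solutions_with_label(scan, "EMP")
  emp <- Filter(function(e) e$set$atp_yield == 1L, emp)
  expect_gt(length(emp), 0)
  expect_identical(net_atp_yield(emp[[1]]$set$directed, emp[[1]]$solution), 1)
})

test_that("net ATP equals the injected yield for every enumerated solution", {
  scan <- fixture_scan()
  for (set in scan$solution_sets)
    for (s in set$solutions)
      expect_identical(net_atp_yield(set$directed, s), as.numeric(s$atp_yield))
})

test_that("strategy classification follows the marker sets", {
  fake <- function(active) structure(list(active_set = active),
                                     class = "pathway_solution")
  expect_true("methylglyoxal" %in% classify_strategy(fake("MGSA_fwd")))
  expect_identical(
    classify_strategy(fake(c("SDAA_fwd", "SERA_fwd", "SERC_fwd", "SERB_fwd"))),
    "serine_shunt")
  # deaminase alone is not enough without the biosynthesis co-requirement
  expect_length(classify_strategy(fake("SDAA_fwd")), 0L)
  expect_length(classify_strategy(fake(character())), 0L)
  expect_identical(classify_strategy(fake(c("PGM_bwd", "ENO_fwd", "PYK_fwd"))),
                   "EMP")
})

test_that("classification ignores flux scale and active-set order", {
  scan <- fixture_scan()
  s <- scan$solution_sets[["0"]]$solutions[[1]]
  base <- classify_strategy(s)
  scaled <- s; scaled$fluxes <- s$fluxes * 3.7
  shuffled <- s; shuffled$active_set <- rev(s$active_set)
  expect_identical(classify_strategy(scaled), base)
  expect_setequal(classify_strategy(shuffled), base)
})

test_that("route segments trace the expected main-carbon sequences", {
  scan <- fixture_scan()
  serine <- solutions_with_label(scan, "serine_shunt")[[1]]
  seg <- route_segment(serine$set$directed, serine$solution, "3pg", "pyruvate")
  expect_identical(seg, c("SERA", "SERC", "SERB", "SDAA"))

  mg <- solutions_with_label(scan, "methylglyoxal")
  pure_gsh <- Filter(function(e) {
    p <- sub("_(fwd|bwd)$", "", e$solution$active_set)
    all(c("MGGSH", "GLOB") %in% p) && !any(c("HCHA", "GLDA") %in% p)
  }, mg)
  expect_gt(length(pure_gsh), 0)
  expect_identical(
    route_segment(pure_gsh[[1]]$set$directed, pure_gsh[[1]]$solution,
                  "mgx", "pyruvate"),
    c("MGGSH", "GLOB", "DLD"))

  pure_hcha <- Filter(function(e) {
    p <- sub("_(fwd|bwd)$", "", e$solution$active_set)
    "HCHA" %in% p && !any(c("MGGSH", "GLDA") %in% p)
  }, mg)
  expect_gt(length(pure_hcha), 0)
  expect_identical(
    route_segment(pure_hcha[[1]]$set$directed, pure_hcha[[1]]$solution,
                  "mgx", "pyruvate"),
    c("HCHA", "DLD"))

  # disconnected query gives a typed status, not an error
  miss <- route_segment(serine$set$directed, serine$solution,
                        "mgx", "pyruvate")
  expect_s3_class(miss, "route_status")
  expect_identical(miss$status, "no_path")
})

test_that("segments stay inside the active set and chain through shared carbon", {
  scan <- fixture_scan()
  for (set in scan$solution_sets) {
    for (s in set$solutions) {
      seg <- route_segment(set$directed, s, "mgx", "pyruvate")
      if (inherits(seg, "route_status")) next
      parents <- sub("_(fwd|bwd)$", "", s$active_set)
      expect_true(all(seg %in% parents))
      expect_gte(length(seg), 2L)
    }
  }
})

test_that("segment-variant counting distinguishes reaction-id sets", {
  scan <- fixture_scan()
  expect_identical(as.integer(count_segment_variants(scan, "mgx", "pyruvate")),
                   3L)
  expect_identical(as.integer(count_segment_variants(scan, "serine",
                                                     "pyruvate")), 1L)
  empty <- structure(list(solution_sets = list()), class = "pathway_scan")
  expect_identical(as.integer(count_segment_variants(empty, "mgx",
                                                     "pyruvate")), 0L)
})

test_that("rational snapping recovers small fractions and leaves others", {
  expect_identical(rationalise(0.5 + 1e-9), 0.5)
  expect_identical(rationalise(-1 + 2e-8), -1)
  expect_identical(rationalise(c(1/3 + 1e-9, 0.25)), c(1/3, 0.25))
  expect_equal(rationalise(pi, max_denominator = 10), pi)
})

test_that("solution export writes JSON, flat TSV, annotations and manifest", {
  out <- withr::local_tempdir()
  net <- build_central_carbon_fixture()
  scan <- run_pipeline(net, out, config = enumeration_config(atp_yields = 1L))
  expect_true(file.exists(file.path(out, "solutions_n+1.json")))
  expect_true(file.exists(file.path(out, "solutions.tsv")))
  expect_true(file.exists(file.path(out, "annotations.tsv")))
  expect_true(file.exists(file.path(out, "manifest.json")))

  annot <- read.delim(file.path(out, "annotations.tsv"))
  expect_identical(annot$strategies[1], "EMP")
  expect_equal(annot$net_atp[1], 1)
  payload <- jsonlite::read_json(file.path(out, "solutions_n+1.json"))
  expect_identical(payload$status, "exhausted")
  expect_identical(payload$solutions[[1]]$cardinality, 10L)

  manifest <- jsonlite::read_json(file.path(out, "manifest.json"))
  listed <- vapply(manifest$outputs, `[[`, character(1), "file")
  expect_true(all(c("solutions.tsv", "annotations.tsv") %in% listed))
  expect_true(all(nchar(vapply(manifest$outputs, `[[`, character(1),
                               "md5")) == 32L))

  # determinism: a re-run into a fresh directory reproduces the tables
  out2 <- withr::local_tempdir()
  run_pipeline(net, out2, config = enumeration_config(atp_yields = 1L))
  expect_identical(readLines(file.path(out, "annotations.tsv")),
                   readLines(file.path(out2, "annotations.tsv")))
})
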