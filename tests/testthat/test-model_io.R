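test_that("fixture JSON reads with the curated dimensions and round-trips", {
  path <- system.file("extdata", "central_carbon.json", package = "thermopath")
  net <- read_model(path, "fixture_json")
  expect_s3_class(net, "metabolic_network")
  expect_length(net$metabolites, 36)
  expect_length(net$reactions, 32)

  tmp <- withr::local_tempfile(fileext = ".json")
  write_fixture_json(net, tmp)
  back <- read_model(tmp, "fixture_json")
  expect_identical(names(back$reactions), names(net$reactions))
  expect_identical(names(back$metabolites), names(net$metabolites))
  for (id in names(net$reactions)) {
    expect_equal(back$reactions[[id]]$stoichiometry,
                 net$reactions[[id]]$stoichiometry)
    expect_identical(back$reactions[[id]]$reversible,
                     net$reactions[[id]]$reversible)
    expect_equal(back$reactions[[id]]$delta_g, net$reactions[[id]]$delta_g)
  }
})

test_that("network validation rejects undeclared metabolites and duplicates", {
  expect_error(
    metabolic_network(list(metabolite("a")),
                      list(reaction("R", c(a = -1, ghost = 1)))),
    "undeclared metabolite")
  expect_error(
    metabolic_network(list(metabolite("a"), metabolite("a")),
                      list(reaction("R", c(a = -1)))),
    "duplicate metabolite")
  expect_error(reaction("R", c(a = 0)), "zero stoichiometric")
  expect_error(reaction("R", numeric()), "empty")
})

test_that("alterations apply in order and validate ids", {
  net <- build_central_carbon_fixture()
  out <- apply_alterations(net, list(list(op = "remove_reaction", id = "TPI")))
  expect_length(out$reactions, 31)
  expect_null(out$reactions$TPI)
  expect_identical(apply_alterations(net, list()), net)
  expect_error(apply_alterations(net, list(list(op = "remove_reaction",
                                                id = "NOPE"))),
               "unknown reaction")
  rev_pyk <- apply_alterations(net, list(list(op = "set_reversibility",
                                              id = "PYK", reversible = TRUE)))
  d <- split_reactions(add_objective_reaction(rev_pyk, objective_spec()))
  expect_true(all(c("PYK_fwd", "PYK_bwd") %in% names(d$reactions)))
  newg <- apply_alterations(net, list(list(op = "set_delta_g", id = "SERA",
                                           value = 12)))
  expect_equal(newg$reactions$SERA$delta_g, 12)
})

test_that("objective injection follows source + n ADP + n Pi -> sink + n ATP", {
  net <- build_central_carbon_fixture()
  n0 <- add_objective_reaction(net, objective_spec(atp_yield = 0L))
  expect_equal(n0$reactions$OBJ$stoichiometry, c(glycerol = -1, pyruvate = 1))

  n1 <- add_objective_reaction(net, objective_spec(atp_yield = 1L))
  expect_equal(n1$reactions$OBJ$stoichiometry,
               c(glycerol = -1, pyruvate = 1, adp = -1, pi = -1, atp = 1))

  nm2 <- add_objective_reaction(net, objective_spec(atp_yield = -2L))
  expect_equal(nm2$reactions$OBJ$stoichiometry,
               c(glycerol = -1, pyruvate = 1, adp = 2, pi = 2, atp = -2))

  expect_error(add_objective_reaction(n1, objective_spec()), "already injected")
  expect_error(objective_spec(source = "x", sink = "x"), "must differ")
  expect_error(
    add_objective_reaction(net, objective_spec(source = "ghost")),
    "missing from network")
})

test_that("the injected conversion is elementally exact for n in -3..3", {
  net <- build_central_carbon_fixture()
  for (n in -3:3) {
    with_obj <- add_objective_reaction(net, objective_spec(atp_yield = n))
    expect_identical(nrow(elemental_imbalance(with_obj)), 0L)
  }
})

test_that("splitting creates one directed copy per direction with mirrored g0", {
  net <- build_central_carbon_fixture()
  with_obj <- add_objective_reaction(net, objective_spec())
  d <- split_reactions(with_obj, beta = 10)
  n_rev <- sum(vapply(net$reactions, `[[`, logical(1), "reversible"))
  n_irr <- length(net$reactions) - n_rev
  expect_length(d$reactions, 2 * n_rev + n_irr)
  expect_false("OBJ_fwd" %in% names(d$reactions))

  fwd <- d$reactions$TPI_fwd; bwd <- d$reactions$TPI_bwd
  expect_equal(bwd$stoich, -fwd$stoich)
  expect_equal(bwd$g0, -fwd$g0)
  expect_false("PYK_bwd" %in% names(d$reactions))

  expect_error(split_reactions(with_obj, beta = 0), "beta must be positive")
  expect_error(split_reactions(net), "no objective reaction")
  d_all <- split_reactions(with_obj, split_irreversible = TRUE)
  expect_length(d_all$reactions, 2 * (n_rev + n_irr))
})

test_that("a thermo-constrained split demands Gibbs energies unless exempted", {
  net <- chain_network(c(-1, -1))
  net$reactions$R1$delta_g <- NA_real_
  with_obj <- add_objective_reaction(net, objective_spec(source = "m1",
                                                         sink = "m3"))
  expect_error(split_reactions(with_obj), "lacks a standard Gibbs energy")
  d <- split_reactions(with_obj, thermo_unconstrained = "R1")
  expect_true(is.na(d$reactions$R1_fwd$g0))
  d2 <- split_reactions(with_obj, require_delta_g = FALSE)
  expect_true(is.na(d2$reactions$R1_fwd$g0))
})

test_that("net directed flux reproduces the parent network's mass balance", {
  net <- build_central_carbon_fixture()
  with_obj <- add_objective_reaction(net, objective_spec(atp_yield = 1L))
  d <- split_reactions(with_obj)
  set.seed(42)
  v <- stats::setNames(runif(length(d$reactions), 0, 2), names(d$reactions))
  # accumulate directed fluxes
  met_ids <- names(net$metabolites)
  resid_directed <- stats::setNames(rep(0, length(met_ids)), met_ids)
  for (dr in d$reactions)
    resid_directed[names(dr$stoich)] <-
      resid_directed[names(dr$stoich)] + dr$stoich * v[[dr$id]]
  # same totals via net parent fluxes on the parent stoichiometry
  resid_parent <- stats::setNames(rep(0, length(met_ids)), met_ids)
  for (pid in names(d$pairing)) {
    pair <- d$pairing[[pid]]
    net_flux <- v[[pair[["fwd"]]]] -
      if ("bwd" %in% names(pair)) v[[pair[["bwd"]]]] else 0
    st <- net$reactions[[pid]]$stoichiometry
    resid_parent[names(st)] <- resid_parent[names(st)] + st * net_flux
  }
  expect_lt(max(abs(resid_directed - resid_parent)), 1e-9)
})

test_that("BiGG-style JSON reads with bound-derived reversibility, drops exchanges", {
  doc <- list(
    metabolites = list(list(id = "glc_c"), list(id = "pyr_c"), list(id = "glc_e")),
    reactions = list(
      list(id = "GLCPYR", metabolites = list(glc_c = -1, pyr_c = 2),
           lower_bound = -1000, upper_bound = 1000),
      list(id = "PYRSINK", metabolites = list(pyr_c = -1),
           lower_bound = 0, upper_bound = 1000),
      list(id = "EX_glc_e", metabolites = list(glc_e = -1),
           lower_bound = -10, upper_bound = 1000)))
  tmp <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(doc, tmp, auto_unbox = TRUE)
  net <- read_model(tmp, "bigg_json")
  expect_identical(names(net$reactions), c("GLCPYR", "PYRSINK"))
  expect_true(net$reactions$GLCPYR$reversible)
  expect_false(net$reactions$PYRSINK$reversible)
  expect_equal(net$reactions$GLCPYR$stoichiometry, c(glc_c = -1, pyr_c = 2))
  kept <- read_model(tmp, "bigg_json", keep_boundary = "EX_glc_e")
  expect_true("EX_glc_e" %in% names(kept$reactions))
})

test_that("SBML L3/FBC reads species, stoichiometry and flux-bound reversibility", {
  sbml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
    'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
    'level="3" version="1"><model id="mini">',
    '<listOfParameters>',
    '<parameter id="lb_free" value="-1000" constant="true"/>',
    '<parameter id="lb_zero" value="0" constant="true"/>',
    '</listOfParameters>',
    '<listOfSpecies><species id="A"/><species id="B"/></listOfSpecies>',
    '<listOfReactions>',
    '<reaction id="RAB" reversible="true" fbc:lowerFluxBound="lb_free">',
    '<listOfReactants><speciesReference species="A" stoichiometry="1"/></listOfReactants>',
    '<listOfProducts><speciesReference species="B" stoichiometry="2"/></listOfProducts>',
    '</reaction>',
    '<reaction id="RBA" reversible="false" fbc:lowerFluxBound="lb_zero">',
    '<listOfReactants><speciesReference species="B" stoichiometry="1"/></listOfReactants>',
    '<listOfProducts><speciesReference species="A" stoichiometry="1"/></listOfProducts>',
    '</reaction>',
    '</listOfReactions></model></sbml>')
  tmp <- withr::local_tempfile(fileext = ".xml")
  writeLines(sbml, tmp)
  net <- read_model(tmp, "sbml")
  expect_identical(names(net$metabolites), c("A", "B"))
  expect_equal(net$reactions$RAB$stoichiometry, c(A = -1, B = 2))
  expect_true(net$reactions$RAB$reversible)
  expect_false(net$reactions$RBA$reversible)
})

test_that("unknown paths and formats fail loudly", {
  expect_error(read_model("no-such-file.json", "fixture_json"), "not found")
  expect_error(read_model(tempfile(), "parquet"))
})
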