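#' Curated central-carbon network of E. coli (glycerol to pyruvate)
#'
#' A single-compartment, 36-metabolite / 32-reaction transcription of the
#' central-metabolism map relevant to glycolysis bypasses: glycerol entry
#' (glycerol kinase, glycerol-3-phosphate dehydrogenase), the
#' Embden-Meyerhof-Parnas trunk, gluconeogenic access to the
#' Entner-Doudoroff pathway (aldolase, FBPase, PGI, a lumped
#' Zwf+lactonase step, Edd, Eda), the three methylglyoxal degradation
#' routes (glutathione-dependent GloA/GloB, direct HchA, and the
#' GldA/AldA/LldD reduction route), the four-enzyme serine shunt
#' (SerA/SerC/SerB/SdaA), and redox/amine closure reactions (glutamate
#' dehydrogenase, transhydrogenase, NADH dehydrogenase, quinol oxidase,
#' adenylate kinase, PEP synthase) so that cofactors balance at steady
#' state without any respiratory ATP synthesis -- ATP accounting is
#' purely substrate-level.
#'
#' Water and protons are omitted entirely (their activities are absorbed
#' in the transformed standard Gibbs energies), so oxygen and hydrogen are
#' not balanced; carbon, nitrogen and phosphorus balance exactly.
#' Standard Gibbs energies are curated stand-in estimates chosen by
#' feasibility class: the 3-phosphoglycerate dehydrogenase step carries
#' the serine shunt's characteristic thermodynamic barrier (+30 kJ/mol)
#' while the committed lower-glycolysis, methylglyoxal and deaminase
#' steps are strongly exergonic. The lumped steps carry `lumped:` tags.
#'
#' @return A `metabolic_network`.
#' @export
build_central_carbon_fixture <- function() {
  el <- function(C = 0, N = 0, P = 0) c(C = C, N = N, P = P)
  mets <- list(
    metabolite("glycerol",   "glycerol",                  el(C = 3)),
    metabolite("glycerol3p", "sn-glycerol 3-phosphate",   el(C = 3, P = 1)),
    metabolite("dhap",       "dihydroxyacetone phosphate", el(C = 3, P = 1)),
    metabolite("gap",        "glyceraldehyde 3-phosphate", el(C = 3, P = 1)),
    metabolite("fbp",        "fructose 1,6-bisphosphate", el(C = 6, P = 2)),
    metabolite("f6p",        "fructose 6-phosphate",      el(C = 6, P = 1)),
    metabolite("g6p",        "glucose 6-phosphate",       el(C = 6, P = 1)),
    metabolite("6pg",        "6-phosphogluconate",        el(C = 6, P = 1)),
    metabolite("kdpg",       "2-keto-3-deoxy-6-phosphogluconate", el(C = 6, P = 1)),
    metabolite("13bpg",      "1,3-bisphosphoglycerate",   el(C = 3, P = 2)),
    metabolite("3pg",        "3-phosphoglycerate",        el(C = 3, P = 1)),
    metabolite("2pg",        "2-phosphoglycerate",        el(C = 3, P = 1)),
    metabolite("pep",        "phosphoenolpyruvate",       el(C = 3, P = 1)),
    metabolite("pyruvate",   "pyruvate",                  el(C = 3)),
    metabolite("mgx",        "methylglyoxal",             el(C = 3)),
    metabolite("lgt",        "(R)-S-lactoylglutathione",  el(C = 13, N = 3)),
    metabolite("gsh",        "glutathione (reduced)",     el(C = 10, N = 3)),
    metabolite("dlac",       "D-lactate",                 el(C = 3)),
    metabolite("lald",       "lactaldehyde",              el(C = 3)),
    metabolite("llac",       "L-lactate",                 el(C = 3)),
    metabolite("php",        "3-phosphohydroxypyruvate",  el(C = 3, P = 1)),
    metabolite("pser",       "O-phosphoserine",           el(C = 3, N = 1, P = 1)),
    metabolite("serine",     "L-serine",                  el(C = 3, N = 1)),
    metabolite("nh3",        "ammonia",                   el(N = 1)),
    metabolite("glutamate",  "L-glutamate",               el(C = 5, N = 1)),
    metabolite("akg",        "2-ketoglutarate",           el(C = 5)),
    metabolite("atp",        "ATP",                       el(C = 10, N = 5, P = 3)),
    metabolite("adp",        "ADP",                       el(C = 10, N = 5, P = 2)),
    metabolite("amp",        "AMP",                       el(C = 10, N = 5, P = 1)),
    metabolite("pi",         "orthophosphate",            el(P = 1)),
    metabolite("nad",        "NAD+",                      el(C = 21, N = 7, P = 2)),
    metabolite("nadh",       "NADH",                      el(C = 21, N = 7, P = 2)),
    metabolite("nadp",       "NADP+",                     el(C = 21, N = 7, P = 3)),
    metabolite("nadph",      "NADPH",                     el(C = 21, N = 7, P = 3)),
    metabolite("q",          "ubiquinone-8",              el(C = 49)),
    metabolite("qh2",        "ubiquinol-8",               el(C = 49)))

  rx <- function(id, st, rev = FALSE, dg, tags = character())
    reaction(id, st, reversible = rev, delta_g = dg, tags = tags)
  rxns <- list(
    rx("GLPK",   c(glycerol = -1, atp = -1, glycerol3p = 1, adp = 1), FALSE, -20),
    rx("GLPD",   c(glycerol3p = -1, q = -1, dhap = 1, qh2 = 1),      FALSE, -30),
    rx("TPI",    c(dhap = -1, gap = 1),                              TRUE,   5.5),
    rx("FBA",    c(dhap = -1, gap = -1, fbp = 1),                    TRUE,  -20),
    rx("FBPASE", c(fbp = -1, f6p = 1, pi = 1),                       FALSE, -11),
    rx("PGI",    c(f6p = -1, g6p = 1),                               TRUE,  -2.5),
    rx("ZWF_L",  c(g6p = -1, nadp = -1, `6pg` = 1, nadph = 1),       FALSE, -25,
       tags = "lumped:zwf+pgl"),
    rx("EDD",    c(`6pg` = -1, kdpg = 1),                            FALSE, -20),
    rx("EDA",    c(kdpg = -1, pyruvate = 1, gap = 1),                FALSE,  16),
    rx("GAPD",   c(gap = -1, nad = -1, pi = -1, `13bpg` = 1, nadh = 1), TRUE, 7.5),
    rx("PGK",    c(`13bpg` = -1, adp = -1, `3pg` = 1, atp = 1),      TRUE,  -19),
    rx("PGM",    c(`3pg` = -1, `2pg` = 1),                           TRUE,   4.2),
    rx("ENO",    c(`2pg` = -1, pep = 1),                             TRUE,  -4),
    rx("PYK",    c(pep = -1, adp = -1, pyruvate = 1, atp = 1),       FALSE, -27),
    rx("PPSA",   c(pyruvate = -1, atp = -1, pep = 1, amp = 1, pi = 1), FALSE, -12),
    rx("ADK",    c(atp = -1, amp = -1, adp = 2),                     TRUE,   0),
    rx("MGSA",   c(dhap = -1, mgx = 1, pi = 1),                      FALSE, -25),
    rx("MGGSH",  c(mgx = -1, gsh = -1, lgt = 1),                     FALSE, -35,
       tags = "lumped:hemithioacetal+gloA"),
    rx("GLOB",   c(lgt = -1, dlac = 1, gsh = 1),                     FALSE, -15),
    rx("HCHA",   c(mgx = -1, dlac = 1),                              FALSE, -50),
    rx("GLDA",   c(mgx = -1, nadh = -1, lald = 1, nad = 1),          FALSE, -35),
    rx("ALDA",   c(lald = -1, nad = -1, llac = 1, nadh = 1),         FALSE, -50),
    rx("LLDD",   c(llac = -1, q = -1, pyruvate = 1, qh2 = 1),        FALSE, -55),
    rx("DLD",    c(dlac = -1, q = -1, pyruvate = 1, qh2 = 1),        FALSE, -55),
    rx("SERA",   c(`3pg` = -1, nad = -1, php = 1, nadh = 1),         TRUE,   30),
    rx("SERC",   c(php = -1, glutamate = -1, pser = 1, akg = 1),     FALSE, -10),
    rx("SERB",   c(pser = -1, serine = 1, pi = 1),                   FALSE, -13),
    rx("SDAA",   c(serine = -1, pyruvate = 1, nh3 = 1),              FALSE, -35),
    rx("GLUDY",  c(akg = -1, nh3 = -1, nadph = -1, glutamate = 1, nadp = 1),
       FALSE, -33),
    rx("THD",    c(nadh = -1, nadp = -1, nad = 1, nadph = 1),        TRUE,   0),
    rx("NDH",    c(nadh = -1, q = -1, nad = 1, qh2 = 1),             FALSE, -80),
    rx("QOX",    c(qh2 = -1, q = 1),                                 FALSE, -100))
  metabolic_network(mets, rxns)
}
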