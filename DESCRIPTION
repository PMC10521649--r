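Package: thermopath
Title: Thermodynamics-Constrained Enumeration of Minimal Metabolic Pathways
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Searches stoichiometric metabolic networks for minimal
    thermodynamically feasible pathways between a source and a sink
    metabolite. A mixed-integer linear program couples steady-state mass
    balance with second-law (driving-force) constraints over bounded
    log-metabolite concentrations, minimises the number of active
    reactions, and enumerates alternative routes per ATP yield with
    radius-limited integer cuts. Includes a curated central-carbon
    network of Escherichia coli covering the Embden-Meyerhof-Parnas,
    Entner-Doudoroff, methylglyoxal and serine-shunt routes from
    glycerol to pyruvate, generators for planted-pathway test networks,
    a brute-force enumeration oracle, and downstream pathway analysis
    (ATP accounting, strategy classification, route-variant counting).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    reticulate,
    pracma,
    igraph,
    xml2,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
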