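# thermopath

Enumeration of minimal, thermodynamically feasible metabolic pathways in
stoichiometric networks — built around the question of which latent routes
in *Escherichia coli* central metabolism can replace canonical
Embden–Meyerhof–Parnas (EMP) glycolysis for the conversion of glycerol to
pyruvate.

## Who this is for

Systems and synthetic biologists who want to search a constraint-based
metabolic model for *alternative* source→sink routes — including
ATP-neutral or ATP-wasting ones that a yield-constrained flux balance
search would never surface — and to post-process the hits into
interpretable strategies (which committed enzymes, which route variants,
what net ATP per product).

## The method

The search is a mixed-integer linear program over a reaction-split
network. Every (unidirectional) reaction *i* carries a rate
`0 ≤ v_i ≤ β` and a binary indicator `z_i`; every metabolite *j* a
log-concentration `x_j` bounded by `ln C_min ≤ x ≤ ln C_max`
(1 µM – 10 mM by default, with 15 central metabolites confined to
physiological ranges). An injected net-conversion reaction

    glycerol + n ADP + n Pi  →  pyruvate + n ATP

has its rate fixed at −1, so the network must supply the conversion at
unit rate for the required ATP yield *n*. The constraints are

    S v = 0                               (steady state, v_obj = −1)
    0 ≤ −g⁰ − Sᵀx + M (1 − z)             (second law, per active reaction)
    v − β z ≤ 0,  εz − v ≤ 0              (indicator coupling)
    z_fwd + z_bwd ≤ 1                     (direction exclusivity)

with `g⁰ = Δ_r G′° / RT` and per-reaction big-M constants tight over the
concentration box. The objective minimises `Σ z_i`, the number of active
reactions. Alternative routes are enumerated per ATP yield with
radius-2 integer cuts — each new solution must differ from every previous
one in more than 2 indicator positions — stopping after 10 solutions per
yield. The MILP is solved with the open-source HiGHS solver (via scipy,
driven through reticulate); an independent brute-force oracle
(exhaustive subset search over two plain-simplex LPs) cross-checks
minimum cardinalities on small networks.

## Worked example

```r
library(thermopath)

net <- build_central_carbon_fixture()
net
#> Metabolic network: 36 metabolites, 32 reactions (10 reversible)

scan <- scan_atp_yields(net, atp_yields = c(-1, 0, 1))
summary(scan)
#> Pathway scan over ATP yields {-1, 0, 1}
#>   n = -1: 10 solution(s), cap_reached
#>   n = 0: 10 solution(s), cap_reached
#>   n = 1: 1 solution(s), exhausted
#> Strategies found: ED, EMP, methylglyoxal, serine_shunt
```

The scan recovers all four broad glycerol→pyruvate strategies: lower EMP
glycolysis (the only +1 ATP family), the Entner–Doudoroff pathway, the
ATP-wasting methylglyoxal bypass (three route variants:
glutathione-dependent GloA/GloB→Dld, direct HchA→Dld, and
GldA→AldA→LldD), and the ATP-neutral serine shunt. Inspecting the serine
shunt at yield 0:

```r
s <- scan$solution_sets[["0"]]$solutions[[3]]
s
#> Pathway solution: 13 active reactions (ATP yield 0)
#>   GAPD_fwd, GLPD_fwd, GLPK_fwd, GLUDY_fwd, NDH_fwd, PGK_fwd, QOX_fwd,
#>   SDAA_fwd, SERA_fwd, SERB_fwd, SERC_fwd, THD_fwd, TPI_fwd

d <- scan$solution_sets[["0"]]$directed
net_atp_yield(d, s)
#> [1] 0
route_segment(d, s, "3pg", "pyruvate", via = "serine")
#> [1] "SERA" "SERC" "SERB" "SDAA"
```

The glycerol kinase ATP is exactly repaid by phosphoglycerate kinase
(net ATP 0) and the shunt itself is the four-enzyme
SerA→SerC→SerB→SdaA segment from 3-phosphoglycerate to pyruvate.
`count_strategies()`, `count_segment_variants()`, `verify_solution()`
and `export_solutions()` cover classification, variant counting,
independent solution checking and disk export; `run_pipeline()` wires
everything together, and `inst/cli/thermopath.R` exposes it from a
shell. Genome-scale models load through `read_model()` (BiGG JSON or
SBML L3/FBC); desk-scale work uses the packaged fixture and the
synthetic generators (`generate_planted_network()`,
`generate_parallel_routes()`).

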