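---
title: "Thermodynamics-constrained minimal pathway enumeration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermodynamics-constrained minimal pathway enumeration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

thermopath searches a stoichiometric network for the shortest
thermodynamically feasible conversion of a source metabolite into a sink
metabolite at a prescribed ATP yield. The formulation couples three
ingredients that are usually treated separately:

1. **Steady-state mass balance.** After splitting every reversible
   reaction into a forward and a backward copy, all rates are
   non-negative: `S v = 0` with the injected net-conversion reaction
   (`source + n ADP + n Pi → sink + n ATP`) fixed at rate −1. Fixing the
   rate rather than bounding it forces the remaining network to supply
   the conversion at exactly unit rate, so fluxes are interpretable per
   unit of product.
2. **The second law.** Each directed reaction *i* carries a standard
   Gibbs energy `g⁰_i` in RT units; a reaction may only be active if
   log-concentrations `x` within the allowed box make it exergonic:
   `−g⁰_i − (Sᵀx)_i ≥ 0`. Linearised with a per-reaction big-M, the
   constraint binds only when the indicator `z_i = 1`. This single
   device excludes futile cycles (no closed loop can be exergonic all
   the way around) and enforces pathway-level feasibility, not merely
   per-reaction plausibility: all active reactions must agree on one
   concentration vector.
3. **Cardinality minimisation and enumeration.** The objective is
   `min Σ z_i`. After each optimum, an integer cut of radius 2 removes
   every indicator vector within Hamming distance 2 of the found active
   set, and the solve repeats until infeasibility or until 10 solutions
   per ATP yield have accumulated.

Assumptions worth keeping in mind: one well-mixed compartment;
concentrations are free variables inside their boxes (no kinetics, no
enzyme cost); ΔrG′° values are inputs, not estimated on-line; ATP
accounting is purely substrate-level because the curated network
deliberately contains no respiratory ATP synthesis.

## Parameters

| parameter | default | units | why |
|---|---|---|---|
| `beta` | 10 | relative rate | cap on any single reaction rate relative to the unit conversion; arbitrary but must exceed realistic per-unit fluxes (the largest observed here is 2) |
| concentration box | 1e-6 – 1e-2 | mol/L | generic metabolite range; span ln 10⁴ ≈ 9.21 RT decides single-reaction feasibility |
| central-metabolite ranges | see `default_metabolite_ranges()` | mol/L | 15 cofactors/central intermediates confined to literature-typical physiological ranges; shipped values are curated stand-ins, replaceable via TSV |
| `cut_radius` | 2 | indicator flips | "within a radius of 2" is read strictly: solutions at distance ≤ 2 are eliminated, so enumerated sets are pairwise ≥ 3 apart; configurable, so the weaker reading is testable |
| `max_solutions` | 10 | count | stopping rule per ATP yield |
| `atp_yields` | −2 … 2 | mol ATP / mol sink | scan set; "each possible ATP yield" is unbounded in principle, but outside this window the curated network is infeasible |
| big-M margin | 1 | RT | safety margin on the per-reaction big-M so the relaxed constraint is strictly vacuous at `z = 0` |
| `flux_epsilon` | 1e-3 | relative rate | minimum rate through an *active* reaction (see below) |
| `tolerance` | 1e-6 | — | flux-support and verification tolerance |
| temperature | 298.15 | K | RT = 2.4790 kJ/mol; the conversion `gibbs_to_rt()` exposes it |

## Design choices that were genuinely open

**Minimum-activity coupling.** The textbook formulation only forces
`v_i ≤ β z_i`. Under integer-cut enumeration that is not enough: a
cut can be satisfied "for free" by switching on indicators whose
reactions carry zero flux, provided their thermodynamic constraint is
satisfiable. Such padded solutions corrupt every downstream statistic
(cardinalities, strategy labels, variant counts). thermopath therefore
adds `flux_epsilon · z_i ≤ v_i`, tying the indicator set to the actual
flux support. With `flux_epsilon = 1e-3` and genuine fluxes of order
0.5–2, the constraint never excludes a real pathway.

**Direction exclusivity.** `z_fwd + z_bwd ≤ 1` is added although the
second law already forbids both directions of a reaction from being
simultaneously exergonic: at `ΔrG′ = 0` both could be active at the
boundary. The explicit constraint removes this degenerate case and
tightens the relaxation.

**Irreversible reactions are not split.** A backward copy of an
irreversible reaction would change the model, so only reversible
reactions yield two directed copies. The flag `split_irreversible`
restores the literal all-reactions reading for sensitivity analysis.

**Second law at equality.** The driving-force constraint permits
`ΔrG′ = 0` (the transhydrogenase step of the serine-shunt solution
operates at this boundary under the shipped concentration ranges). A
strict mode is a one-line change of `tolerance` in verification.

**Route segments through waypoints.** `route_segment()` returns the
shortest main-carbon path (cofactor nodes removed) in the active
subnetwork. Solutions that combine strategies can shadow a longer
segment with a shorter competing one — a hybrid carrying both lower EMP
and the serine shunt reaches pyruvate from 3-phosphoglycerate in three
steps via enolase. The optional `via` waypoint ("through serine")
recovers the segment the strategy is named after. Variants are counted
as distinct reaction-id sets, so cofactor-swapped routes (quinone- vs
NAD-linked lactate oxidation) count separately.

**ATP accounting by ATP coefficients.** `net_atp_yield()` sums
`v_i ·` (ATP coefficient); PEP synthase (ATP → AMP) counts −1 with
adenylate kinase closing the AMP balance. Sums are snapped to exact
small rationals (continued fractions) so yields are reported as 0, −1,
+1 rather than solver-precision floats.

## The curated fixture and what it does (not) show

`build_central_carbon_fixture()` transcribes the part of *E. coli*
central metabolism relevant to glycolysis bypasses: 36 metabolites and
32 reactions covering glycerol entry, the EMP trunk, gluconeogenic
access to the Entner–Doudoroff pathway, all three methylglyoxal
degradation routes, the four-enzyme serine shunt, and redox/amine
closure (transhydrogenase, NADH dehydrogenase, quinol oxidase,
glutamate dehydrogenase, adenylate kinase, PEP synthase). Water and
protons are omitted — their activities live inside the transformed
standard energies — so C, N and P balance exactly and O/H are not
tracked. Two steps are lumped (glucose-6-phosphate dehydrogenase with
the lactonase; the spontaneous hemithioacetal formation with
glyoxalase A) and carry `lumped:` tags so segment lengths remain
interpretable.

The packaged ΔrG′° values are curated stand-ins chosen by feasibility
class: the 3-phosphoglycerate dehydrogenase step carries the serine
shunt's characteristic +30 kJ/mol barrier (feasible only near the
corners of the physiological ranges), committed steps like pyruvate
kinase or the deaminase are strongly exergonic. Tests assert these
classes, not the decimal values, so re-deriving energies from any
component-contribution estimator should not break them.

What passing on this fixture does **not** show: behaviour on a
genome-scale model (thousands of reactions, compartments, transport),
robustness of the 15 shipped concentration ranges (the values any
specific study used are a supplementary-level detail; ours are
literature-typical), or anything kinetic. The fixture demonstrates the
mechanism at a scale where every claim can be cross-checked by
exhaustive enumeration.

## Synthetic generators and the oracle

`generate_planted_network()` plants a unique shortest source→sink chain
(exergonic steps, −5 to −1 RT) among random distractor reactions; each
distractor is accepted only after the brute-force oracle confirms the
planted chain is still the unique minimum. This rejection step makes
the generator's guarantee *constructive* rather than probabilistic.
`generate_parallel_routes()` builds fully disjoint routes (pairwise
indicator distance `2 × route length`) for exercising the stopping rule
in isolation. Neither generator models noise: the analysis is
deterministic, so the synthetic module plants structure, not
statistical variation.

The oracle (`brute_force_enumerate()`) tests subsets in increasing
cardinality with two elastic LPs per subset — flux feasibility at rates
in `[flux_epsilon, beta]`, then a max-min driving-force feasibility
check over the concentration box — on a plain simplex implementation
entirely independent of the HiGHS MILP path. It is guarded to ≤ 20
directed reactions; agreement with the MILP is asserted over 50 seeded
networks.

## Numerical choices and problem sizes

Dense constraint matrices are used throughout: the fixture MILP has
~120 variables and ~180 rows, far below any sparsity threshold. HiGHS
runs with `mip_rel_gap = 0`, making enumerated cardinalities exact.
Tie-breaking among equal-cardinality optima is solver-dependent; all
results are treated as sets and all tests are order-insensitive up to
cardinality. The simplex LPs in the oracle are shifted to non-negative
variables with bound rows (the implementation used mishandles negative
lower bounds) and posed in elastic form, so "infeasible" is always read
off a bounded optimum rather than from solver error paths.

Default test and acceptance runs use the 36×32 fixture scanned over
yields {−1, 0, 1} (~25 MILP solves), a 12-route stopping-rule network,
50 planted networks of ≤ 12 directed reactions, and a five-point
analytic feasibility sweep — sizes chosen so every quantity the package
reports is recomputed from scratch in well under a minute on one CPU.

## Known limitations

- No max–min driving force optimisation: feasibility only, as in the
  underlying search strategy.
- No gene–protein–reaction rules, compartments or biomass handling;
  genome-scale SBML/BiGG inputs are read, exchange reactions dropped,
  compartment suffixes treated as distinct metabolites.
- The supplementary alteration list of the original genome-scale run is
  not public; `apply_alterations()` is a schema-complete hook.
- Enumeration beyond the 10-per-yield cap (e.g. aggregating "more than
  100" routes with variant expansion) is supported only through the
  distinct-segment counter, not by exhausting the solution space.
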