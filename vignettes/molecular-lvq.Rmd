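---
title: "Molecular LVQ networks: model, kinetics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Molecular LVQ networks: model, kinetics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(molvq)
```

## The model

`molvq` implements a learning vector quantization (LVQ) classifier whose
inference pass is executed by a DNA strand-displacement (DSD) reaction
network. An LVQ model consists of `j` prototype vectors `b_j` (one per
competitive-layer neuron), each wired to exactly one of `l` output classes.
A sample `a` is classified by the prototype nearest in Manhattan distance,

    d_j = sum_i |a_i - b_ij|,

and the class of the argmin-`j` prototype is reported. Training (LVQ1) is
conventional silicon-side optimisation: the nearest prototype is pulled
toward a matching-label sample by `alpha (a - w)` and pushed away on a
mismatch. The molecular contribution is the inference network: numbers are
carried as strand concentrations in nM, and the argmin is computed
chemically.

The compiled network has eight reaction modules in three layers:

1. **Input layer.** *Input activation* catalytically releases input strands
   `X_ij` and weight strands `W_ij` (or `NW_ij` for negative weights) from
   their substrates; *subtraction annihilation* consumes matched `X`/`W`
   pairs one-for-one through a cooperative-hybridization gate, leaving
   `|a_i - b_ij|` of the majority strand; *absolute-value summation* funnels
   the residues of all `i` channels into the distance factor `D_j`.
2. **Competitive layer** (loser-take-all). *Signal reversal* splits each
   `D_j` evenly over `n - 1` reversal factors; *reverse summation* collects
   them into reverse signals `S_k = (sum_j d_j - d_k)/(n - 1)`, so the
   smallest distance becomes the largest signal; *annihilation* consumes the
   `S_k` pairwise until effectively one survives.
3. **Output layer.** *Report summation* routes each surviving `S_k` to its
   class's reporter, and the *reporting reaction* irreversibly displaces the
   fluorophore strand `Y_l`, the measured output.

## Kinetic conventions

Three toehold classes set every rate: G (7 nt) binds at 9e7 M^-1 s^-1 and
unbinds at 0.1 s^-1; H and T (5 nt) bind at 3e5 M^-1 s^-1 and unbind at
26 s^-1. Internally all bimolecular constants are converted to nM^-1 s^-1
(factor 1e-9); concentrations are nM, time is seconds.

* Strand-releasing reversible displacements are bimolecular in both
  directions, forward at the initiating toehold's binding rate and reverse
  at the binding rate of the toehold exposed on the products.
* The binding-only first step of a cooperative (two-input) gate is
  bimolecular forward and unimolecular reverse at the toehold's unbinding
  rate; the second input's arrival is irreversible.
* Subtraction and loser-take-all annihilation run on G; the first summation
  step runs on H and the second on T; the report-summation step is H and
  the final reporter step T. The G/H binding ratio of 300 is what makes
  annihilation dominate summation, which is the design's central
  requirement.
* The fuel-regeneration step of the catalytic input-activation cycle is
  irreversible: its waste is a toehold-free duplex that cannot re-invade.
  This is also required thermodynamically — with every step reversible at
  symmetric rates the cycle would stall near half conversion, whereas the
  design calls for complete substrate turnover (verified in the tests to
  within 1%).
* A leak mode adds, per designed bimolecular reaction, a parallel channel at
  the global leak rate of 1 M^-1 s^-1. It is off by default. This is a
  declared simplification: it does not emulate the spurious polymer
  pathways a sequence-level simulator would enumerate, so leak-driven
  crosstalk between unrelated gates is out of scope.

## Gate concentration recipe

For input `a` and signed weights `b` (all in nM after affine scaling of each
feature onto `[0, range_max]`, default 1000 nM):

| species | concentration |
|---|---|
| `IN_i`, `XSUB_ij` | `a_i` |
| `WSUB_ij` | `|b_ij|` |
| `XFUEL_i` | `200% * sum_j (a_i + |b_ij|)` |
| `SG_ij` | `120% * max(0, min(a_i, b_ij))` |
| `SUMX_ij`, `SUMW_ij` | `120% * |a_i - b_ij|` |
| `SUM_j` | `120% * sum_i |a_i - b_ij|` |
| `SRG_jk`, `RSG_k` | `100% * max_j d_j` |
| `ANH_kj` | `120% * max_k s_k` |
| `RE_kl` | `100% * max_k s_k` |
| `R_l` | `150% * max_k s_k` |

Negative weights flow through `|a - b| = a + |b|`, need no special casing in
the summation gates, and emit no subtraction gate (the `NW` strand does not
match the gate's branch-migration domain). The fuel concentration sums over
`j` because one fuel species per input channel must turn over the substrates
of every prototype sharing that channel.

## Simulation

`simulate()` integrates the mass-action ODE system with a BDF stiff solver
(`deSolve::vode`) and the analytic Jacobian assembled from the
stoichiometric matrix; rate constants span nine orders of magnitude, so
stiffness is the norm. Defaults: `rtol = 1e-8`, `atol = 1e-12` nM, 600
output points, endpoint read at exactly `t_end` (30000 s for diagnosis,
10000 s for the loser-take-all fixtures) regardless of the steady-state
flag. The right-hand side is evaluated without clamping: occasional negative
excursions stay within the absolute tolerance and produce restoring fluxes,
and the smooth derivative lets the solver take large steps. Because fluxes
enter only through the stoichiometric matrix, every left-null-space
conservation law holds along trajectories to integrator precision; the test
suite audits a drift bound of 1e-6 relative on every run it checks.

## Synthetic data

Two generators stand in for the cohorts the reference workflow draws from
public repositories (which this package deliberately does not download):

* `gen_morphology_like()` — two-class Gaussian cohort, ten features, default
  357 + 212 cases, class centers 400 and 600 nM with sd 100 nM: a strongly
  but not trivially separable nucleus-morphology-like problem on the working
  concentration scale.
* `gen_expression_like()` — two-class log-normal cohort, default 875 + 1006
  cases, baseline median 100, `sdlog = 0.35` (roughly a 36% CV, typical of
  serum biomarker panels), two-fold median shift on five of ten features.
  With these settings a held-out LVQ fit reaches ~95% accuracy and the
  null (no-shift) cohort sits at chance, which is the regime the generator
  is meant to emulate.

Neither generator reproduces the covariance structure, batch effects, or
feature heterogeneity of the real data sets, so passing tests demonstrate
correct mechanics of the pipeline, not clinical performance.

`module_fixtures()` fixes the module-level operating points: per range
r in {10, 100, 1000} nM the input/weight combinations `X = W = r`,
`0.2r/0.8r`, `0.8r/0.2r` for both weight signs, and eight loser-take-all
triples with `D_1` minimal. Positive-weight fixtures use all four gates at
`1.2 r` as in the reference module experiments; negative-weight fixtures use
the recipe gates `1.2 (X + |NW|)` — for the split combinations that equals
`1.2 r`, and for `X = NW = r` it is the only choice under which the total
summation gate can represent the ideal distance `2r` at all. The
loser-take-all triples enforce at least two-fold gaps between consecutive
inputs because the competitive circuit is accurate only away from the
close-competitor regime (see Limitations); gates are 100 nM
(reversal, reverse summation, report summation), 108 nM (annihilation) and
150 nM (reporter).

## Numerical and design choices

* **Distance metric in training.** Manhattan, matching the molecular layer,
  so the silicon decision boundary is the one the chemistry implements.
* **LVQ1 schedule.** `alpha(e) = lr0 (1 - (e-1)/epochs)` with `lr0 = 0.1`,
  `epochs = 100`; prototypes initialise from random samples of their class;
  per-class prototype counts allocated proportionally (largest remainder,
  minimum one). All configurable; the reference workflow is silent on these,
  so they are package choices, inspectable via `default_config()`.
* **Cross-validation.** `kfold_select_prototypes()` uses stratified folds,
  `k = 5` by default, ties broken toward fewer prototypes.
* **Ties.** Nearest-prototype ties go to the lowest prototype index and are
  flagged; a molecularly symmetric tie suppresses both outputs and the
  diagnosis is reported undetermined.
* **Diagnosis call.** Argmax of the reporter endpoints; undetermined when
  the outputs cannot be normalized, the normalized winner is below 0.5, or
  the top two outputs are within 10% relative. Displayed normalized values
  are rounded to two decimals; raw values are retained.
* **Error convention.** Module errors are `100 |final - ideal| / range_max`
  (full scale, not relative to the ideal), which is the only convention
  under which a residual on an ideal-zero fixture has a finite error.
* **Census convention.** `census()` counts the reagent strands a network
  requires — substrates, fuels and gates — excluding the activation factors
  `IN_i`, which carry the sample itself (in the expression workflow they
  are the converted biomarker strands), and excluding transient
  intermediates and waste. For the (10, 3, 2) network with all-positive
  weights this gives 180 distinct strands; counting the `IN_i` as reagents
  would give 190.
* **Problem sizes.** The test suite runs the full fixture set, a 40-sample
  end-to-end agreement suite at shape (10, 2, 2), and single compiled
  (10, 3, 2) networks; these sizes exercise every code path at full
  kinetic fidelity while keeping a complete run in the minutes range.

## Limitations

* The loser-take-all layer dilutes reverse-signal differences by
  `1/(n - 1)` and shares its reactants with the reporting layer, so for
  three or more competitors whose smallest two distances are within roughly
  a factor of two, the molecular call degrades and can disagree with the
  silicon classifier — especially when one class fields two prototypes
  whose reporter sums against a lone opponent. The two-prototype network
  (one per class) does not suffer this dilution and tracks the silicon
  label essentially everywhere the distance gap is resolvable. This mirrors
  the documented behavior of the physical circuits; it is a property of the
  architecture, not of the integrator.
* With every concentration scale expressed through bimolecular steps, the
  fraction of an input-equals-weight pair that escapes annihilation into
  the summation channel is nearly scale-invariant (~3-4% of full scale at
  30000 s across the three ranges in the ideal X = W stress case, under 1%
  for split combinations and 0.06% for negative weights). A sequence-level
  simulator with explicit branch-migration intermediates quenches the
  high-concentration residual somewhat faster; this difference only matters
  in the degenerate X = W corner.
* No nucleotide sequences, secondary structure, crosstalk, or stochastic
  (SSA) semantics: the network is an idealized mass-action object, exactly
  as compiled.
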