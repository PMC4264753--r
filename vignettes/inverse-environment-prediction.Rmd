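---
title: "Inverse prediction of growth environments from internal metabolic fluxes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inverse prediction of growth environments from internal metabolic fluxes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxinvert)
```

## The question

Constraint-based metabolic modeling usually runs forward: given a growth
environment, flux balance analysis (FBA) computes a steady-state flux
distribution. `fluxinvert` runs the question backwards: given only the
*internal* fluxes of a cell — no exchange fluxes, no transporter fluxes —
can the growth environment (which carbon source, which nitrogen source)
be recovered? The package simulates labeled flux data under composed
environments and fits sparse multinomial classifiers to answer that
question, together with the evaluation battery needed to interpret the
answer: misclassification rates against impurity load and training size,
confusion structure, the identity of the predictive reactions, ablation
of those reactions, restricted (entry-point-only) predictor sets, and
extrapolation to substrates never seen in training.

## The forward model

A metabolic model is a stoichiometric matrix $S$ (metabolites $\times$
reactions), flux bounds $l \le v \le u$ (mmol gDW$^{-1}$ hr$^{-1}$), and a
biomass objective $c$. FBA solves the linear program

$$\max_v \; c^\top v \quad \text{s.t.} \quad S v = 0, \; l \le v \le u .$$

A growth environment enters exclusively through exchange-reaction lower
bounds: the primary carbon and nitrogen sources are opened at
$-20$ mmol gDW$^{-1}$ hr$^{-1}$ (the conventional maximum uptake), each
randomly drawn impurity at $1/100$ of that ($-0.2$), oxygen at $-18.5$
when the model has an oxygen exchange, and every other candidate
carbon/nitrogen exchange is closed. All remaining bounds — ions, forced
maintenance fluxes — are untouched by `apply_environment()`.

Observations whose biomass does not exceed a viability threshold are
discarded as non-growing. The threshold is defined as the mean minus
three sample standard deviations of a reference biomass distribution
(`compute_viability_threshold()`); whether the original convention used
the sample or population standard deviation is not documented anywhere we
could find, so the sample version was chosen and the multiplier `k_sd` is
an argument. The genome-scale reference value 0.558 is the default in
`simulation_config()`; toy-model runs normally pass their own threshold
(or 0, since toy biomass is far from zero whenever the network grows).

### The LP solver

No linear-programming package is available in this environment
(`boot::simplex` exists but fails with internal errors on FBA-structured
problems), so the package carries its own dense two-phase primal simplex
for bounded variables (`R/lp.R`): Dantzig pricing with a smallest-index
tie-break, a Bland's-rule fallback that guarantees termination, basis
inverse maintained by elementary row updates with periodic
refactorization, and pivot/feasibility tolerances of $10^{-7}$/$10^{-9}$.
It was validated against brute-force vertex enumeration on small networks
(a property test that ships with the package) and, during development,
against an independent HiGHS implementation on random bounded LPs. All
model bounds are finite (the conventional $\pm 1000$ sentinel encodes
"unconstrained"), so the LP is never unbounded and the only non-optimal
outcome is infeasibility, which the simulator records as biomass 0 (then
removed by the viability filter) rather than aborting a batch.

FBA optima are degenerate in general: many vertices attain the same
biomass. The solver is deterministic — identical problems yield identical
vertices — so replicate-to-replicate variation in a simulation comes only
from impurity sampling. `minimize_total_flux()` exposes the parsimonious
canonicalization: minimize $\sum_i |v_i|$ at fixed optimal biomass, as an
LP over split positive/negative flux parts. The biomass pin is an exact
equality row solved at the simplex tolerance, which keeps the realized
biomass within $10^{-9}$ of the requested value.

## The inverse model

Internal reactions are the predictors. `classify_reactions()` removes:

* **exchange** reactions — boundary pseudo-reactions touching exactly one
  metabolite;
* **transport** reactions — subsystem annotation matching `"transport"`
  case-insensitively, *or* moving the same chemical species between
  compartments (BiGG `_c`/`_e`/`_p` suffixes; the suffix regex is an
  argument for non-BiGG naming). Either signal suffices: annotation
  catches PTS-style transporters that chemically modify their substrate,
  stoichiometry catches unannotated carriers;
* the **biomass** reaction — the unique reaction with nonzero objective
  weight; several such reactions raise an error rather than a guess.

Everything else is internal. Predicting from exchange or transport fluxes
would be reading the environment off the cell surface; the scientific
content of the exercise is that the *interior* of the network still
carries the signal.

Flux magnitudes below $10^{-6}$ are set to exactly zero before fitting
(`build_features()`), a numerical hygiene step for the coordinate-descent
fit. Labels are either the carbon source, the nitrogen source (separate
mode), or the `"carbon|nitrogen"` pair (joint mode; a joint prediction is
correct only when both components are).

`train_flux_classifier()` fits L1-penalized multinomial logistic
regression with glmnet (symmetric multinomial parameterization,
standardized features, $\alpha = 1$, i.e. the LASSO) over the usual
decreasing penalty path, and selects $\lambda$ by $K$-fold
cross-validated misclassification ($K = 3$ by default, fold assignment
stratified by class and seeded). Two deliberate deviations from
`cv.glmnet` are worth recording. First, CV errors are computed by an
explicit fold loop using the package's own hard-label rule — argmax of
the per-class linear scores with ties broken toward the earlier class —
because `cv.glmnet`'s class-error measure scores exact probability ties
as correct, and with perfectly balanced folds that makes the *null* model
look perfect and collapses the penalty selection. Second, the selected
$\lambda$ is the largest value attaining the minimum CV error (the
conventional choice; no one-standard-error rule, since the selection rule
documented for this analysis is the minimum itself). With $K$ set to the
number of observations the same loop performs leave-one-out CV, which a
test verifies against an independent brute-force implementation.

The reactions with a nonzero coefficient for at least one class at the
selected penalty are the *predictive reactions*
(`predictive_reactions()`). `ablation_study()` retrains with one of them
removed at a time — same seed, same selection procedure, so the delta
reflects the removal alone. `novel_substrate_protocol()` scores data
simulated with a substrate absent from training and tabulates which known
class absorbs it. `select_distinct_substrates()` picks a panel of
substrates with well-separated impurity-free flux signatures by k-means
(`stats::kmeans`, seeded, restarted) and returns the member closest to
each centroid, deduplicating exactly repeated profiles first so
duplicates can never split across clusters.

## The synthetic benchmark

Reproducing the genome-scale analysis requires the iAF1260 model, a
download this package deliberately does not bundle. Every pipeline stage
is instead exercised on generated toy networks
(`generate_toy_model()`), built to emulate the structural features that
make inverse prediction possible and hard:

* per substrate, one exchange and one transport reaction, then a
  *private* linear pathway of `pathway_length` reactions (default 3);
* pathways of the same role (carbon or nitrogen) converge on a shared
  tail — a TCA-like core — controlled by `overlap` $\in [0,1]$: the
  shared tail has `round(overlap * pathway_length)` reactions. At
  `overlap = 0` every substrate leaves a fully private internal
  signature; at `overlap = 1` the transport step feeds the common
  pathway directly (as phosphotransferase transporters do), internal
  fluxes are identical across same-role substrates, and no classifier
  can beat the $1 - 1/k$ chance rate — the package returns the explicit
  null model in that degenerate case;
* a core of `core_size` reactions (default 4, split between the carbon
  and nitrogen branches) converts the two precursors into the inputs of
  a biomass reaction consuming one unit of each.

All stoichiometric coefficients are $\pm 1$, so the optimum has a closed
form at `overlap = 0` (`toy_ground_truth()`): biomass is the smaller of
total carbon and total nitrogen supply, the limiting side saturates its
uptake bounds, and a non-limiting side with a single open substrate
carries exactly the biomass flux. These closed forms are the oracle for
the FBA tests. With equal impurity counts on both sides the two supplies
tie, every uptake saturates, and the optimum is unique — so the only
stochasticity in a simulated dataset is *which* impurities were drawn,
mirroring the structure of the original study design (deterministic
solver, random chemical noise).

Defaults follow the study conditions wherever they are stated: 7 carbon
and 7 nitrogen sources in the reference panel, 100 replicates per
condition at full scale, primary uptake $-20$, impurities at $-0.2$,
excess scenarios at $-1000$ on one side. The toy runs in the tests and
the acceptance script use 10–20 replicates per condition and an overlap
of 0.2, sizes chosen so a full pipeline completes in tens of seconds on
one core while leaving every qualitative contrast (impurity degradation,
separate-vs-joint, predictive-reaction recovery) intact; the replicate
count only narrows confidence bands, it does not move the contrasts.

What the toy cannot show: realistic E. coli topology (loops,
cofactor coupling, alternate routes of unequal length), genuine LP
degeneracy among alternate optima, substrates that feed both carbon and
nitrogen metabolism, and realistic viability structure (toy biomass is
essentially never near the threshold). Passing the toy suite therefore
demonstrates the correctness of the machinery and the qualitative
phenomenology, not genome-scale error rates; the genome-scale tier of
the acceptance tests runs only when an iAF1260 BiGG JSON is supplied via
`options(fluxinvert.iaf1260 = )`.

## Numerical and design choices

* **Simplex tolerances**: reduced-cost tolerance $10^{-7}$, ratio-test
  and feasibility tolerance $10^{-9}$; phase-1 residual above $10^{-6}$
  declares infeasibility. Mass-balance residuals of accepted solutions
  are test-asserted below $10^{-6}$.
* **Impurity sampling** is uniform without replacement and *excludes the
  primary sources*: a duplicated primary would silently raise its uptake
  bound. Only-carbon or only-nitrogen impurity designs are expressed as
  `k_N = 0` or `k_C = 0`.
* **Train/test splitting** is stratified by (carbon, nitrogen) condition
  — the 49-class joint model is untrainable at small sizes otherwise —
  with the test half drawn per stratum and training subsets taken
  round-robin across strata so every condition keeps representation at
  any `train_size`. The viability filter runs before the split.
* **Ties in prediction** go to the earlier class in training-label
  order; predictions are invariant to adding a constant to all
  intercepts (softmax shift invariance, test-asserted).
* **Seeding**: every stochastic entry point takes an explicit seed and
  restores the caller's RNG state on exit, so package calls never
  perturb user-level randomness; a dataset is bit-reproducible from its
  seed.
* **Serialization**: flux datasets as plain CSV (labels + one column per
  internal reaction) with a JSON manifest; classifiers as JSON holding
  the nonzero coefficient triplets at the selected penalty, enough to
  predict and to extract predictive reactions, but not the full path.

## Limitations

The LP solver is dense and intended for models up to a few hundred
reactions; genome-scale models load and classify fine (sparse matrices
throughout `model_io`), but solving them is far slower than a production
sparse-revised-simplex and is the main obstacle to running the
genome-scale tier routinely. The classifier inherits glmnet's
convergence behavior for near-separable data (warnings are expected and
benign on cleanly separable toys). The novel-substrate protocol reports
nearest-known-class frequencies; it does not attempt open-set detection.
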