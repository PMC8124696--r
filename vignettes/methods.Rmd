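---
title: "Methods: risk and decision analysis for PM2.5 increase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: risk and decision analysis for PM2.5 increase}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pm25decide)
```

This vignette explains the statistical model behind `pm25decide`, the
choices the package makes where the methodology is genuinely open, and
what the synthetic-data generator does and does not emulate.

## The pipeline and its assumptions

The pipeline connects three classical tools — event-tree risk analysis,
expected-value/expected-utility decision analysis, and a weighted
additive multi-criteria model — into one chain for the question "how
likely is ambient PM2.5 to rise, and which emission sector should
receive mitigation investment?".

Its standing assumptions are:

* **Independent risk factors.** The joint distribution over factor
  levels is the product of the marginals. Population, economy and
  temperature interact in reality (ports grow with trade, energy demand
  with population); the event tree ignores this, so joint-path
  probabilities are first-order approximations.
* **Discretized uncertainty.** Continuous increase-rate beliefs are cut
  into High/Medium/Low levels, and consequences likewise. Everything
  downstream sees only the discretization.
* **Linear monetization.** The benefit of removing PM2.5 mass is linear
  in mass at a fixed benefit-per-ton rate (2010 USD), with no discounting
  or inflation adjustment. The air volume `V` is symbolic: every monetary
  output is homogeneous of degree 1 in `V` (a tested invariant), so
  rankings and ratios are V-free and the package defaults to `V = 1`.
* **Exponential utility.** Risk attitude enters only through the single
  risk-tolerance parameter `R` of `u(v) = 1 - exp(-v/R)`.

## Risk structure

A `rate_curve()` is a piecewise-linear CDF through elicited knots.
Linear interpolation is the minimal assumption when only a drawn curve
is available; it makes `level_probabilities()` exact differences of
interpolated CDF values, reproducible against a fine-grid differencing
oracle to 1e-9 in the tests. Curves must start at cumulative probability
0 and end at 1, so every binning that spans the curve's range yields a
proper distribution (enforced at 1e-9).

Level bins are half-open `[lower, upper)` with the topmost bin closed.
Published bin tables print touching edges (0.6% ends one interval and
starts the next); resolving shared edges upward makes membership
unambiguous and is applied uniformly to rate bins and MCDA rank bins.

The packaged LA-LBMA curves are *reconstructions*: the published figure
shows curves graphically without coordinates, so each curve is pinned to
reproduce the stated High-level probabilities (population 0.50, economy
0.70, temperature 0.41) at the bin boundaries, with one interior knot
chosen per curve as a smooth, plausible shape. They are labelled
`derived` in the configuration, and no headline number depends on the
interior knots — only on the bin-boundary values.

## Event tree and risk rating

`enumerate_paths()` computes all joint level tuples exactly (27 leaves
for three factors at three levels); with dozens of leaves there is no
reason to sample, so conditionals are exact sums. A leaf may map to a
single consequence category or to a distribution over categories; both
conserve total probability to 1e-9 (tested across 100 random Dirichlet
trees).

The conditional risk table holds both directions:
`P(consequence | factor = level)` by restricted enumeration and
`P(factor = level | consequence)` by Bayes' rule. For trees built from
an explicit map the two are consistent by construction (a tested
invariant, along with the law of total probability and invariance under
factor reordering). The published LA-LBMA table, however, is carried
*verbatim*: its forward column is not consistent with the published
consequence distribution under the law of total probability, so no
underlying tree can reproduce it and the package does not pretend to
infer one. `reconstructed_tree()` offers a best-effort severity-score
tree (High level = 2 points, Medium = 1, summed; ≥ 4 High, ≥ 2 Medium)
for exploration and property tests only.

Two published-data quirks are handled explicitly rather than silently:

* The consequence distribution prints 0.49/0.42/0.097, which sums to
  1.007. `as_consequence_distribution()` stores it verbatim by default
  (so downstream numbers match the published ones) with an opt-in
  `renormalize` flag.
* `bayes_invert()` clips quotients above 1, warns, and flags the result,
  because verbatim inputs need not be jointly consistent.

`select_critical_factor()` is an argmax over
`P(factor = High | consequence = High)`; ties within 1e-12 are reported
and broken by input order, never silently.

## Valuation

Unit handling is fixed once: 1 metric ton = 1e12 µg, so
`mass = reduction (µg/m³) × V (m³) × 1e-12` tons. The per-scenario
monetary value is the triple product success probability × $/ton × mass.

Expected utility is computed per scenario by default —
`EU = Σ P_i u(MV_i)` — because that matches the structure of the
published utility table; the aggregate form `u(EMV)` is also exposed.
With monetary values of order 1e-7 and tolerances of 5–200 the two agree
to three significant figures (tested), and `R·EU → EMV` as `R → ∞`
(tested at relative 1e-5 when `max(MV)/R ≤ 1e-7`), so EMV and EU
rankings coincide in that regime.

The electricity-generating units sector is published with two different
scenario-probability vectors (0.55/0.40/0.05 in the elicitation table,
0.45/0.40/0.15 in the EMV summary); only the latter reproduces the
published EMV. The configuration uses the latter and carries the former
as `elicited_scenario_prob` metadata, with a warning on load.

## MCDA and sensitivity

Rank bins map raw assessments to ranks 1–4; the score is
`max_rank + 1 − rank`. The published tables state ranks and scores but
not the mapping between them; `5 − rank` is the unique affine reflection
reconciling them (rank 1 ↔ score 4), and it is order-reversing in rank
by construction (tested exhaustively for bin counts 1–6). Criterion
direction follows the rank tables (smaller $M/ton ranks 1, hence scores
highest) even though "investment efficiency" prose could be read either
way; the tables are taken as the authoritative preference encoding.
Raw assessments in the packaged case use bin midpoints, since the
published scorecard states bins, not point values; any value inside the
bin produces the same rank and score.

The decision score `DS = Σ CW_j S_j` is affine in the weight vector, so
over the three-criterion weight simplex
`{(x, y) : x, y ≥ 0, x + y ≤ 1}` each alternative's score field is a
plane and extremes occur at vertices (tested). `sensitivity_surface()`
evaluates a regular grid (default step 0.01 in weight units — fine
enough to locate any boundary to 1% of weight at negligible cost:
5151 points for three alternatives run in milliseconds) and flags
argmax ties below 1e-12 rather than breaking them silently.
`decision_boundary()` gives the exact pairwise half-plane
`coef_x·x + coef_y·y + intercept > 0` by subtracting score vectors, so
grid claims can be cross-checked analytically; on the packaged case the
refineries/electricity boundary is exactly `y = 0.5` and ocean-going
vessels dominate everywhere, with a single tie at the vertex
`(x, y) = (0, 1)` where all weight sits on implementation difficulty
and both ocean-going vessels and electricity-generating units score 3 —
dominance on the open simplex is strict, but not at that boundary point.

## Synthetic generator

`generator_config()` plus `random_cdf()`, `random_event_tree()`,
`random_decision_problem()` and `random_mcda_instance()` produce random
but structurally valid inputs for every stage, so all property tests run
without any external data. Choices, made once:

* **Dirichlet(1) simplex sampling** for branch/scenario probabilities —
  uniform over the simplex, the least-informative valid choice.
* **Log-uniform $/ton** over 5e4–4e5 by default, exercising the
  order-of-magnitude spread seen across real sector benefit-per-ton
  estimates.
* **Sorted-uniform CDF knots** with pinned 0/1 endpoints, giving
  arbitrary monotone piecewise-linear curves, with an optional symmetric
  band that always brackets the central curve.
* Determinism: each generator reseeds from `config$seed`, so identical
  configurations give bitwise-identical cases (tested).

What the generator does **not** emulate: temporal structure (no PM2.5
time series or demographic trajectories), dependence between factors,
realistic elicitation artifacts (probabilities that do not sum to 1,
inconsistent conditional tables — those exist only in the verbatim
case), or correlations between a sector's cost and its success
probability. Passing property tests therefore demonstrates mathematical
correctness of the pipeline on valid inputs, not robustness to the
messiness of real elicitation, which is exactly why the verbatim
published tables ship alongside as a separate fixture.

## Numerical conventions

* Probability sums validated at 1e-9; argmax/tie comparisons at 1e-12.
* Reported headline values are rounded to 3 significant figures for
  display only; full precision is kept internally and in reports.
* Degenerate inputs error early with the offending field's path (e.g.
  `decision/alternatives[2]/scenario_prob`): zero-probability
  conditioning, empty rankings, out-of-bin assessments, non-monotone
  curves, weights not summing to 1.
* Test problem sizes: 3 factors × 3 levels (27-leaf trees), 100 random
  seeds for property suites, 0.01 simplex grid — all chosen because the
  methods are exact enumeration and run in milliseconds; nothing is
  approximated for speed.

## Limitations

* The verbatim conditional risk table cannot be audited against a
  generating tree (the published inputs are internally inconsistent);
  the package surfaces this rather than resolving it.
* Benefit-per-ton values are exogenous 2010-USD constants; no inflation
  adjustment, discounting, or health-impact modelling.
* The MCDA is a plain weighted additive model over rank scores — no
  outranking, AHP, or interaction terms — and inherits the usual
  sensitivity of rank-bin methods to bin-edge placement.
* Uncertainty bands on the rate curves are carried and sampled but do
  not propagate into interval-valued downstream results; point estimates
  only.
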