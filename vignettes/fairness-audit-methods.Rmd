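---
title: "Methods: fairness auditing, bias mitigation and SCIR simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fairness auditing, bias mitigation and SCIR simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fairdx)
```

fairdx bundles four things that are usually scattered across ad-hoc
scripts in clinical fairness studies: a synthetic cohort generator with
controllable group structure, a group-fairness metric suite, post-processing
bias-mitigation operators, and deterministic compartmental epidemic models
used to reason about population-level consequences of biased risk
prediction. This vignette records the models, the defaults and the design
decisions — including the places where a published formula family is
ambiguous and we had to choose.

## The synthetic cohort

`generate_cohort()` emulates tabular cardiovascular screening data: age in
days, height, weight, systolic/diastolic pressure, ordinal cholesterol and
glucose (1–3), binary lifestyle flags, gender (1 = women, 2 = men) and a
binary outcome. Defaults are a 10,000-subject cohort with marginals typical
of public data of this schema (35% men, 8.8% smokers, mean age ≈ 53 years)
and the headline dependence structure of such data: age–outcome r = 0.24,
gender–smoking r = 0.34, age–cholesterol r = 0.15, weight–outcome r = 0.18,
glucose–cholesterol r = 0.45, smoking–outcome r = −0.02.

Dependence is induced by a Gaussian copula. Because thresholding a latent
normal attenuates correlation, each requested *observed* Pearson r is
translated into a latent correlation by solving
`achieved_r(rho) = target_r` with `uniroot()`. The achieved correlation has
a one-dimensional integral form: for any pair of margins,
`E[f(Z1) g(Z2)] = ∫ f(z) E[g(Z2) | Z1 = z] φ(z) dz`, and for thresholded
margins the inner conditional expectation is a closed-form `pnorm`
expression, so no two-dimensional quadrature is needed. The resulting
latent matrix is projected to the nearest correlation matrix if the
calibrated entries ever leave the positive-definite cone.

Choices worth flagging:

* **Group-conditional outcomes.** The outcome's latent variable is
  thresholded per gender at `qnorm(1 - rate_g)`, so
  `outcome_rate_by_group` is honoured exactly in expectation. A
  consequence: the gender–outcome association is determined by those rates,
  and a target correlation for that pair is rejected rather than silently
  fought over.
* **Blood pressure.** Diastolic pressure is generated as systolic minus a
  truncated-normal pulse-pressure gap (mean 45, sd 10, floor 5 mmHg), so
  `ap_hi >= ap_lo` holds for every generated row. Real data of this schema
  contains inversions; cleaning rules are a property of data ingestion, not
  of the generative model, so the generator does not emit them.
* **Pack-years.** Smokers receive cigarettes-per-day ~ round(N(15, 7))
  (floored at 1) and a smoking duration capped by age − 18; never-smokers
  have exactly 0 pack-years. Bins are half-open \[0,10), \[10,20),
  \[20,∞) — the printed category labels ("0–10", "10–20", ">20") do not
  state boundary ownership, and half-open intervals make the map total and
  single-valued.
* **Bias factors.** `generate_bias_factors()` draws per-group
  multiplicative transmission adjustments from N(mean, sd) with a default
  mean of −0.10 (a 10% transmission reduction). The normal model is a
  declared choice; nothing deeper than "realistic spread around the stated
  mean effect" is claimed for it.

What passing tests on this generator do **not** show: real screening data
has missingness, measurement error spikes (e.g. swapped pressure digits),
cohort drift and many-way interactions none of which are emulated. The
generator supports inference about the *pipeline* (metric correctness,
mitigation behaviour, determinism), not about any real population.

## Fairness metrics

All metrics operate on a `labeled_predictions()` tibble (true label, score,
predicted label, group) and follow the unprivileged-minus-privileged sign
convention; ratios are unprivileged/privileged. Rates with empty
denominators raise errors naming the group — degenerate silent values (a
disparate impact of exactly 0 because one group never receives a positive
prediction) are precisely how broken audits look plausible.

The Theil index is the generalized-entropy index with α = 1 applied to
per-subject benefits `b_i = ŷ_i − y_i + 1` (the convention of the standard
fairness toolkits): `T = mean((b/μ) log(b/μ))` with `0·log 0 = 0`. It is 0
iff all benefits are equal, e.g. for perfect prediction.

"Difference in mean outcomes" takes the outcome column as an explicit
argument (`"true"` or `"pred"`) because dataset-level and model-level
audits legitimately use different columns; `fairness_report()` reports
both.

## Mitigation operators

**Reweighting** is `w_i = 1/p(y_i|x_i)` with the probability taken from the
baseline classifier for the *observed* label and clipped to `[1e-3, 1]`, so
weights are bounded by 1000.

**Balanced probability adjustment (BPA)** rescales scores by
`1 + α·ΔTPR + β·ΔFPR` and re-thresholds (strictly, at θ = 0.5 by default).
Two modes exist deliberately:

* `"literal"` applies that single factor (≥ 1) to every subject. This is
  the formula as usually printed, and it can only move both groups' rates
  in the same direction — it cannot, by construction, bring two groups
  toward each other.
* `"directed"` (pipeline default) signs the terms per group: the group with
  the lower TPR has its scores raised by the `α·ΔTPR` term and the group
  with the higher FPR has its scores lowered by the `β·ΔFPR` term, each
  sign mirrored for the opposite group. This is the variant that can
  actually reduce disparities, and the discrepancy with the literal formula
  is surfaced in the API rather than papered over.

Two properties of multiplicative score rescaling deserve honesty:

1. It addresses *calibration-type* group bias — one group's scores shifted
   relative to its true risk, so that group's TPR **and** FPR sit below (or
   above) the other's. When disparities are *anti-aligned* (one group worse
   on both error rates, as under differential feature informativeness), any
   monotone rescaling of one group's scores trades one gap against the
   other; no choice of α, β fixes that, and the package's property tests
   plant the calibration mechanism, in a low-prevalence screening regime
   (FPRs of order 0.01, FNRs of order 0.3), because that is the regime the
   operator is meant for.
2. Adjustment strength is proportional to the measured disparity. When the
   measured disparity is sampling noise, the adjustment is noise too; the
   audit-level guarantee is therefore stated (and tested) for baseline gaps
   that exceed their sampling error, not for arbitrary fluctuation.

**Equalised-odds scaling** multiplies non-target-group scores by `k`.
`find_k()` selects `k` by brute-force grid search minimising
`|ΔTPR| + |ΔFPR|` after re-thresholding — the selection rule is not part of
the printed method, so the least surprising one (exhaustive search with
ties broken toward k = 1, the least intervention) was adopted. Because
k = 1 is always in the default grid, the chosen objective never exceeds the
unadjusted one.

**Counterfactual search** discretises the feature box at caller-supplied
steps and enumerates exhaustively, returning the L2-nearest feasible point
or an explicit not-found result. At desk scale exhaustive enumeration is an
exact oracle; no gradient or heuristic search is attempted, and ties in
distance are broken by grid order for determinism.

## Compartmental models

Three deterministic ODE systems over a closed population:

* SIR: `dS = −βSI`, `dI = βSI − γI`, `dR = γI`;
* SCIR, confirmation variant: `dS = −βSI`, `dC = βSI − αC`,
  `dI = αC − γI`, `dR = γI`;
* SCIR, carrier variant: identical structure with the C→I rate named δ.

The transmission term is **unnormalised** by default. The reference state
values this package reproduces (S = 3.58, C = 4.21 at t = 1.02 from
(4, 4, 1, 1) with β = 0.1) are only consistent with `−βSI`: the normalised
form would give dS/dt = −0.04 at the initial state, far too slow to reach
3.58 by t = 1.02. A `normalised = TRUE` flag provides the `−βSI/N` form,
and the two agree when N = 1. In the carrier variant, transmission is
driven by I (not by C); this too is fixed by exact reproduction of the
t = 1.02 state.

`epi_integrate()` wraps `deSolve::ode()` (LSODA by default) with
`rtol = 1e-8`, `atol = 1e-10` and verifies conservation
`|S+C+I+R − N0| < 10·atol` at every output time. The right-hand side
passed to the solver is unvalidated on purpose: adaptive steppers probe
states a rounding error below zero, where the flow field is still
perfectly well defined.

One numerical point matters for the reference trajectories. Under
(β, δ, γ) = (0.5, 0.2, 0.15) the susceptible pool collapses to order
1e-12 — ten thousand times smaller than any practical absolute tolerance.
Digits at that magnitude are *solver-configuration-defined*, not
flow-defined: tighter tolerances give a different (smaller) number, and no
tolerance short of 1e-15 gives a converged one. The package therefore pins
a reference configuration, `scir_reference_solver()`: LSODA at its
conventional default tolerance `rtol = atol = 1.4901161e-8` on the uniform
50-point grid over \[0, 50\] (spacing 50/49 ≈ 1.0204 — which is why the
reported evaluation times are 1.02, 2.04, 4.08, 45.92). All sub-tolerance
susceptible values quoted in the README are defined under exactly this
configuration; quantities above tolerance (R = 9.98, I = 0.0184, the
t = 1.02 state) are configuration-independent at their reporting precision,
which the test suite checks by halving tolerances.

Trajectory summaries: total recoveries are `R(T) − R(0)` (equivalently the
integrated recovery flux); "total cases" has no standard definition at this
level, so the default is initial infected plus integrated flux into I, with
`"final_cumulative"` (initial I + initial C + total outflow from S)
selectable. The summary-level *recovery rate* is the ratio
recoveries/cases — it can legitimately exceed 1 when individuals who start
in C recover during the window without ever being counted as new cases —
and is deliberately distinct from the per-capita rate γ.

`sensitivity_sweep()` integrates one trajectory per parameter row,
records per-row failures without aborting the sweep, and is order-stable.
`scir_sensitivity_grid()` holds the three reference configurations
(0.1/0.05/0.03, 0.3/0.1/0.1, 0.5/0.2/0.15).

## Segmentation and annotation agreement

Pixel coordinates are 0-based with half-open extents, so a (w, h) box has
area exactly `w·h`; the annotation schema does not state a convention and
this one makes areas exact. Dice and IoU are related by
`Dice = 2·IoU/(1 + IoU)` on every pair, which the tests verify against
brute-force pixel counting. Cohen's kappa uses the binary marginal
frequencies of each annotator for expected agreement; two identical
constant masks (chance agreement 1) are defined as κ = 1. A pair of empty
masks raises an undefined-metric error rather than returning a
convention — silent conventions corrupt aggregates.

The detector-level proxies `iou_from_pr()` (mean of precision and recall)
and `iou_avg()` (mean of mAP values) are implemented verbatim but live in
a separate namespace from geometric IoU and are labelled proxies: the two
notions are numerically different and must never be substituted for each
other.

## The audit pipeline

`run_audit()` chains generate/load → jointly stratified 80/20 split →
logistic baseline → fairness report → mitigations → re-audit → optional
epidemic simulation. Design choices:

* The split stratifies jointly on (outcome, group) so small-group rates
  stay defined in both halves; fairness metrics are computed on the test
  split.
* The baseline is an unpenalised maximum-likelihood logistic regression —
  deterministic, calibrated, and sufficient for a score-producing
  reference model; no hyperparameter search is in scope.
* No multiple-testing adjustment is applied: raw metric values are
  reported with full provenance (config hash, seeds, package version) so
  any correction can be applied downstream.
* Every bundle contains the baseline report, so mitigation effects are
  never reported without their reference point.

## Problem sizes used in the test suite

Property tests run at the sizes the claims are stated for: metric oracles
on 1000 random instances of up to 50 subjects; mask identities on 1000
random 16×16 pairs; conservation on 100 random parameter draws;
planted-gap recovery and mitigation monotonicity on 10,000-subject cohorts
over 20 seeds. The full suite completes in about a minute on one core.

## Known limitations

* The copula calibration targets pairwise correlations only; higher-order
  dependence is whatever the Gaussian copula implies.
* Directed BPA and equalised-odds scaling are group-level monotone
  transformations; they cannot repair anti-aligned or within-group
  disparities, and they operate on measured rates, inheriting their
  sampling noise.
* The ODE models assume a closed population with constant rates; no
  stochastic (Gillespie) variant and no parameter fitting to data are
  provided.
* mAP over detection sets is out of scope; only the scalar proxies are
  implemented.
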