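---
title: "Design, simulation and estimation for a quadruplet-blocked cluster trial with embedded placebos"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Design, simulation and estimation for a quadruplet-blocked cluster trial with embedded placebos}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quadtrial)
```

## The design this package models

`quadtrial` implements the statistical machinery of a two-stage cluster
randomized trial of financial incentives for COVID-19 vaccination run across
six rural districts in Ghana. The design is unusual in two ways that drive
everything in the package:

1. **Two-stage cluster randomization with population blocking.** Within each
   district, candidate villages are ranked by population and each run of four
   consecutive villages forms a *quadruplet*. Thirteen quadruplets per
   district are sampled with probability proportional to their share of the
   quadruplet-eligible population, and within each selected quadruplet the
   four villages are randomly assigned one arm each: placebo video, standard
   health-message video, low cash incentive, or high cash incentive.
2. **Embedded placebos for spillover identification.** Inside every treated
   village, 25% of the sampled participants are shown the placebo video
   instead of the village's video. Comparing these embedded placebos with
   participants in placebo villages identifies within-village spillover;
   a separately recruited sample of untreated residents identifies spillover
   onto the non-sampled population.

Three binary outcomes are analyzed by intention to treat: stated vaccination
intention (measured immediately), self-reported vaccination (~2 months
later, by phone or in person), and record-verified vaccination (from
district health office records, with vaccinations after the incentive
window coded as unvaccinated).

## Randomization algorithm and its conventions

The published description leaves a few micro-decisions open; the package
fixes them as follows and treats them as part of the design's law (the
randomization-inference module re-draws assignments under exactly this law):

* Population ranking is descending, with ties broken by village id, so the
  plan is a pure function of (village table, quadruplets per district, seed).
* Districts whose village count is not a multiple of four exclude the
  leftover smallest villages; they are reported, not silently dropped.
* Weighted sampling without replacement is by sequential draws with weight
  renormalization after each draw (the law of `sample(prob = )`).
* The 25% embedded placebo is a fixed per-village count `round(0.25 n)`
  (R's half-to-even rounding), not a per-individual Bernoulli coin. With the
  design's 21 participants per village this yields 5 embedded placebos and
  16 treated; the fixed count guarantees the within-village split and
  removes needless variance from re-randomization draws.
* One master integer seed spawns per-district (and per-quadruplet,
  per-village) substreams, so any stage can be replayed independently.

The field team's manual adjustment of the quadruplet selection in
consultation with district officials is deliberately not modeled; the pure
weighted draw is used.

## The synthetic population

The generator exists so that every estimator can be exercised, calibrated
and validated without the trial's participant-level data. Its defaults *are*
the study conditions:

* **Villages.** Populations follow a log-normal truncated to [30, 5428]
  with `meanlog` solved so the truncated median is 1,040 (`sdlog = 1`).
  Six districts, 200 candidate villages each by default; 13 quadruplets
  selected per district gives the fielded 312-village design.
* **Participants.** 21 per selected village. Covariates reproduce the
  published phase-I marginals: binary shares directly (57.1% female, 28.4%
  WhatsApp, employment and education shares), continuous covariates as
  truncated normals whose *truncated* mean/SD match the published rows
  (age 37.4/16.4 truncated at the eligibility age of 18; weekly food spend
  161.6/99.7 at zero; and so on). Covariates are drawn independently — the
  published table reports marginals only, so no dependence structure is
  asserted.
* **Outcomes.** Each outcome follows a logistic-normal random-intercept
  model. Calibration is exact by construction: given a target intracluster
  correlation on the observed (ANOVA) scale, the latent intercept SD is
  solved by quadrature (`sigma_for_observed_icc()`), and each arm's
  conditional log-odds is then solved so its *marginal* rate equals the
  published arm rate (`mu_for_marginal()`). Defaults: intention rates
  71.0/72.5/81.7/78.2 with ICC 0.15; reported rates 36.3/38.5/41.9/38.1
  with ICC 0.06; verified rates 28.4/21.6/40.7/25.9 with ICC 0.64.
* **The verified ICC of 0.64.** An ICC that extreme for a binary outcome is
  best read as verification-coverage heterogeneity across districts (the
  published district odds ratios run as low as 0.01), not genuine
  village-level clustering. The generator therefore places 80% of the
  verified outcome's latent between-cluster variance in a district-level
  intercept shared by a district's villages. Village-level ANOVA still sees
  the total, so the 0.64 calibration is preserved, but users should note —
  as the coverage study below does — that village-clustered standard errors
  are not designed for district-dominant dependence.
* **Reported versus verified.** The published arm rates, ICCs and spillover
  panels for the two outcomes cannot be produced simultaneously by deriving
  one outcome from the other with fixed misreporting rates, so by default
  the three outcomes are calibrated independently. A configurable misreport
  link (`trial_outcome_params(misreport = list(fp, fn))`) instead derives
  reported status from verified status by directional flips, for users who
  want individual-level consistency at the price of the reported-arm
  calibration.
* **Spillover.** Embedded-placebo and untreated-resident effects are
  expressed as target marginal rates and converted to conditional log-odds
  shifts; the verified defaults use the published spillover panels (e.g.
  38.3% for embedded placebos in low-cash villages).
* **Attrition.** Missingness is logit-modeled, missing-at-random given arm
  and covariates. Defaults are intercept-only at the published retention
  counts: 4,101/5,900 recontacted (~30% attrition) and 3,075/5,900 verified
  (~48%). Arm and covariate coefficients are exposed for MAR stress tests;
  MNAR mechanisms are deliberately out of scope.

What passing tests on this generator do **not** show about real data: the
generator has no covariate dependence, no household structure, no spatial
realism beyond distance computations, and exactly the assumed logistic-normal
dependence; it validates the estimators' design-based properties, not the
substantive findings.

## Estimators

* **Arm rates and contrasts.** `arm_rate()` classifies participants by the
  video actually seen (embedded placebos count in the placebo column, as the
  published tallies do). `diff_in_means_clustered()` is the two-sided
  cluster t-test: the difference of size-weighted arm proportions, standard
  error from the between-cluster variance of cluster means (exactly a
  weighted OLS of cluster means on an arm dummy), `df = g_a + g_b - 2`.
* **ICC.** `icc_anova()` is the one-way ANOVA estimator on the 0/1 scale —
  the convention under which 0.15 / 0.06 / 0.64 are comparable — with a
  Smith/Swiger large-sample interval and a cluster-bootstrap fallback. The
  latent-scale ICC is available separately via `latent_icc()`.
* **Multi-variable models.** `fit_logistic_clustered()` fits the published
  logistic forms (treatment dummies, embedded-placebo dummies, untreated
  indicators, covariates with the reporting scalings age/10 and food/50,
  district indicators) by maximum likelihood and computes the
  village-clustered sandwich covariance in-package: per-cluster score sums,
  `G/(G-1)` small-sample factor (CR1). Odds-ratio intervals use normal
  quantiles on the log scale by default, with a `t(G-1)` option. No
  multiple-testing adjustment is applied anywhere, matching the published
  analysis; p-values are unadjusted throughout.
* **Spillover.** `spillover_contrasts()` produces both contrast families and
  the three model forms (full treated sample with embedded dummies, the
  placebo-video-restricted model, the untreated-sample model). Without
  covariates the restricted model's shared coefficients equal the full
  model's — the cell-mean likelihood factorizes — which the tests exploit as
  an algebraic consistency check.
* **Balance, attrition, IPW, sensitivity.** `smd_balance()` uses pooled-SD
  standardization for continuous covariates and raw proportion differences
  for binaries, flagging at the conventional 0.1. `attrition_logit()` fits
  the three published attrition-model forms; because arms are village-level,
  village fixed effects absorb the arm dummies, so the village-FE variant
  reports within-village covariate effects and a quadruplet-FE variant keeps
  arms identified. `ipw_reestimate()` reweights retained records by inverse
  predicted retention (weights necessarily at least 1), trimmed at the 99th
  percentile by default. `district_sensitivity()` refits a model dropping
  each district in turn.

## Randomization inference

`ri_pvalue()` holds outcomes and village structure fixed, re-draws the
within-quadruplet arm permutation and the embedded-placebo positions through
the same code path as the original assignment, and reports the two-sided
Monte-Carlo p-value with the `+1` finite-sample correction
`p = (1 + #{|T_b| >= |T_obs|}) / (B + 1)`. Quadruplet membership is held
fixed — the design conditions on it — and the default is `B = 2000`. The
published description calls these "bootstrapped simulations"; this module
implements assignment re-randomization (design-based inference), and labels
it as such.

## Power

`simulate_power()` reproduces the pre-registered simulation-based power
analysis: per replicate, arms are assigned within quadruplets through the
design's law, village probabilities follow the calibrated logistic-normal
model, and the pooled-cash versus placebo cluster t-test is run at
`alpha = 0.05`. "Effect size" is an absolute risk difference (all the
published contrasts are percentage points). The pre-registration's assumed
baseline rate, ICC and test are not stated in the text, so the defaults —
baseline 0.36 (the placebo reported-vaccination rate), observed-scale ICC
0.02, two-sided 0.05 — are declared package assumptions, all exposed as
arguments. `analytic_power()` is the closed-form cross-check: a
two-proportion normal approximation with sample sizes deflated by the
design effect `1 + (m - 1) ICC`. A requested village count is rounded to
whole quadruplets (310 becomes 312, mirroring the 13 x 6 x 4 design that
fielded 310 villages).

## Numerical choices and degenerate inputs

* Quadrature for marginal rates and observed ICCs uses adaptive integration
  on [-9, 9] standard deviations with `rel.tol = 1e-10`; calibration roots
  are found with `uniroot` at tolerance 1e-9.
* A zero-variance contrast reports `p = 1` when the difference is zero
  (identical arms) and `p = 0` otherwise; contrasts require at least two
  clusters per arm.
* An all-constant outcome makes the ICC undefined: `NA` with a warning.
* Rank-deficient design matrices raise an error naming the aliased columns;
  probable separation (boundary fitted probabilities with large
  coefficients) raises a warning and a diagnostics flag.
* `round(0.25 n)` uses R's half-to-even convention; the published text does
  not say how fractional embedded-placebo counts were resolved in the field,
  so the count rule is a declared convention.

## Problem sizes used in the shipped checks

The test suite and acceptance script run everything at the design's own
scale where that is cheap (312 villages x 21 participants), and at reduced
replicate counts chosen for tight-enough Monte-Carlo error: 500 replicates
for power and for the size/coverage studies, 200 for the odds-ratio
coverage and IPW bias studies, 100 for ICC recovery, `B` between 199 and
10,000 for randomization inference. Each such choice is stated next to the
check it supports.

## Known limitations

* Covariates are independent; joint-distribution features (and therefore
  realistic covariate-adjusted coefficients) are not emulated, so published
  covariate odds ratios are not reproduction targets.
* Village-clustered inference is exercised under village-level dependence;
  under the district-dominant verified-outcome generator, village-clustered
  standard errors understate uncertainty — by design, as a documented
  caution rather than a defect.
* The BART heterogeneity analysis, propensity-score weighting internals and
  the manual field adjustments to quadruplet selection are out of scope.
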