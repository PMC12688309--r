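---
title: "Parallel multiple mediation of temperature effects on overweight"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parallel multiple mediation of temperature effects on overweight}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

Does ambient temperature affect the prevalence of overweight, and if so,
how much of that effect travels through behaviour? climmed implements a
parallel multiple-mediator analysis for province-clustered survey data in
which the exposure X is the annual mean 2m air temperature of an
individual's province (degrees C), the outcome Y is overweight (BMI >= 25,
binary; obesity, BMI >= 30, is analysed the same way), and two mediators
operate in parallel:

* M1 — adequate fruit/vegetable consumption (>= 5 servings/day, binary);
* M2 — physical-activity level (low / moderate / high, with low as the
  reference), which contributes two pathways, one per non-reference level.

## The model

Three structural equations are fitted by maximum likelihood, all on the
log-odds scale and all adjusted for sex, age (years, uncentred) and
education (four categories, university as reference):

1. `logit P(M1 = 1) = alpha_1 + a1 X + covariates`
2. `log P(M2 = k) / P(M2 = low) = alpha_2k + a2k X + covariates`,
   a multinomial logit with k in {moderate, high};
3. `logit P(Y = 1) = alpha_y + c X + b1 M1 + b21 [M2 = moderate] +
   b22 [M2 = high] + covariates + u_province`,
   with `u_province ~ N(0, sigma^2)` a latent provincial contextual
   variable integrated out by adaptive Gauss–Hermite quadrature.

The three equations share no parameters and the random intercept enters
only the outcome equation, so equation-by-equation maximum likelihood
factorises the joint (generalized structural equation) likelihood exactly;
nothing is lost by not fitting the system jointly.

Effects are decomposed on the coefficient (log-odds) scale:

* direct effect: `c`;
* specific indirect effects (product of coefficients): `a1 b1`,
  `a21 b21`, `a22 b22`;
* per-path total effects: `c + a b`;
* raw difference between indirect pathways: `a1 b1 - a2i b2i`, the
  contrast used to compare mediator importance.

Products of logit coefficients are not collapsible effect measures; we
keep the coefficient scale deliberately (it is the scale on which the
published decompositions are defined) and do not rescale to probabilities
or odds ratios. That is a known limitation of this version.

Inference for the decomposition uses the percentile bootstrap: each
replicate resamples rows with replacement, refits all three equations, and
recomputes every estimand; the 95% interval is the pair of 2.5th/97.5th
order statistics of the replicates. A difference in magnitude between two
indirect effects is declared when that interval excludes zero (strictly:
an endpoint exactly at zero does not exclude it). Percentile intervals —
not BCa — are used because the decision rule and the reported endpoints
are defined on plain percentiles, and the replicate histograms are part of
the standard output.

## The synthetic-cohort generator

The survey microdata behind this design are available only on request, so
the package ships a generator that reproduces the *statistical structure*
the analysis assumes and serves as the test bed for every downstream
stage. Its defaults are the study conditions:

* 24 provinces spanning 4.6–23.0 degrees C. The default layout is a
  deterministic equispaced grid over that range (a `uniform_random` mode
  exists); the real gradient is geographically clustered, which the grid
  does not imitate, but the fitted equations only see the per-province
  scalar.
* Structural slopes equal to the fitted coefficients of the published
  model: a1 = 0.020, a21 = −0.015, a22 = −0.059, b1 = 0.025,
  b21 = −0.168, b22 = −0.362, c = −0.019 for overweight, with province
  variance sigma^2 = 0.026; the obesity equation uses b1 = 0.018,
  b21 = −0.234, b22 = −0.413, c = −0.021.
* Covariate marginals from the sample mix: 57.6% female; age from a
  normal(46.1, 17.9^2) truncated to [18, 95] years; education shares
  17.3 / 10.0 / 36.0 / 36.6% (university, incomplete primary, incomplete
  secondary, complete secondary).
* Mediator missingness: fruit/vegetable status is masked completely at
  random at rate 455/16410 ≈ 2.77%, mirroring the published exclusion.

### Intercept calibration

The published tables print slopes but no intercepts, and without
intercepts the generator's prevalences are undetermined. The package
therefore calibrates intercepts by deterministic root finding
(`calibrate_intercepts()`) against the sample's marginal prevalences:
overweight 67.9%, physical activity 47/36/18% (low/moderate/high), and
adequate fruit/vegetable consumption 6% — the published table's
fruit/vegetable cell counts are internally inconsistent (their margins do
not reconcile), so the approximate 6% marginal is used and the cells are
never used as anchors. The obesity equation is calibrated to 32.4%, the
national survey's published measured-obesity prevalence for the same
year, since the analysis tables do not print it. The calibration
objective, `marginal_prevalence()`, integrates the structural equations
over the covariate distributions (enumeration over province, sex and
education; 24-node Gauss–Legendre quadrature over age), the mediator
states, and the N(0, sigma^2) random intercept (21-node Gauss–Hermite) —
no sampling, so calibration is exact (tolerance 1e-6 on each prevalence)
and idempotent. Binary intercepts are solved by Brent's method on
[−40, 40]; the two multinomial intercepts jointly by a damped Newton
iteration with a numerical Jacobian.

### Randomness and reproducibility

A single integer seed drives generation. Each sampling stage (province
assignment, random intercepts, sex, age, education, M1, M2, outcomes,
missingness mask) draws under its own sub-seed derived from the master
seed and a fixed stage index, so adding a new stage can never perturb the
draws of earlier stages, and identical configurations give bit-identical
cohorts. Ages are drawn by inverse-CDF so the truncated-normal is exact.

### What the generator does and does not emulate

It reproduces the structural equations, the clustering, the covariate
marginals and the missingness rate. It does not reproduce: the survey's
multistage sampling design and weights (the published analysis also did
not apply weights), geographic autocorrelation of temperature, covariate
effects on the mediators (the published mediator blocks print only the
temperature coefficient, so those default to zero — the analysis still
adjusts for covariates in every equation, which is harmless when the
generating effect is null), correlation between the two outcomes beyond
shared predictors, or any latent BMI continuum (outcomes are generated
directly as binary, as modelled). Passing tests on synthetic cohorts
therefore demonstrate correctness of the estimation and inference
machinery under the assumed data-generating process, not robustness to
survey-design features the generator omits.

## Numerical choices

* **Logistic fits** use IRLS with tolerance 1e-12; perfect separation,
  constant responses and rank-deficient designs raise errors rather than
  returning boundary estimates.
* **Multinomial fits** are Newton–Raphson on the categorical
  log-likelihood (relative tolerance 1e-10, gradient below 1e-7,
  step-halving safeguard), warm-started from `nnet::multinom`; this
  pins the optimum tightly enough that the two-level reduction agrees
  with binary logistic to 1e-8.
* **Random-intercept fits** use adaptive Gauss–Hermite quadrature with 7
  points by default — the standard accuracy/speed compromise for a single
  scalar random effect; the test suite verifies the log-likelihood moves
  by less than 1e-6 when the order is doubled. The variance component's
  SE comes from a central-difference Hessian of the deviance over
  (theta, beta) with the delta method SE(sigma^2) = 2 sigma SE(sigma).
* **Bootstrap refits** run on pre-built model matrices through the
  package's Newton solvers (logistic IRLS and multinomial Newton–Raphson),
  warm-started at the full-data estimates. The outcome equation inside replicates defaults to plain
  logistic (`quadrature_points = 0`): with sigma^2 ≈ 0.026 the
  attenuation of mediator coefficients from omitting the random intercept
  is an order of magnitude below their sampling error, while the saving
  makes thousand-replicate runs feasible; passing
  `quadrature_points >= 1` routes every replicate through the multilevel
  fit. Replicates that fail (a category absent from a resample, or
  coefficients past ±50 log-odds, i.e. numerical separation) are dropped
  and counted; more than 1% failures raises a warning, or an error in
  strict mode.
* **Percentile endpoints** are type-1 (order-statistic) quantiles, so the
  reported CI endpoints are always actual replicate values.
* **Raw-difference sign**: the contrast is computed exactly as defined,
  `indirect(M1) − indirect(M2i)`; an absolute-value mode is provided for
  magnitude comparisons. (The published tables print signs for two of
  these contrasts that are inconsistent with their own coefficient
  products; the package does not attempt to guess the intended
  convention.)
* **Descriptives** default to Welch's t-test (a pooled-variance option
  exists) and Pearson chi-squared without continuity correction.

## Problem sizes used in the shipped checks

The package's own validation runs at sizes chosen to make the Monte-Carlo
noise small relative to the tolerances being asserted: generator-vs-oracle
prevalence checks at n = 200,000; coefficient recovery over ten seeded
cohorts of n = 16,000 (the study's sample scale) fitted with 7-point
quadrature; bootstrap coverage over 200 simulated datasets of n = 5,000
with 200 replicates each. The headline bootstrap in the published design —
replicates of 10,000 rows, 5,000 replications — is the package default
(`n_reps = 5000`), and both numbers are ordinary arguments.

When comparing empirical prevalences of a 24-province cohort with the
deterministic oracle, note that the binomial standard error understates
the sampling variability: the 24 realised random intercepts shift the
cohort-level prevalence jointly. The shipped checks add that
between-province component (delta method through the intercept
sensitivity) to the standard error before asserting agreement.

## Known limitations

* Effects are compared on the log-odds coefficient scale only; no
  counterfactual (natural direct/indirect) effect definitions, no
  exposure–mediator interactions, no unmeasured-confounding sensitivity
  analysis.
* Survey weights and design features are intentionally unsupported.
* The temperature exposure is one scalar per province; no raster or
  within-province variation handling. A `temperature_column` switch in
  the pipeline supports sensitivity runs with an alternative per-province
  summary (e.g. the median) supplied as a column.
* Random slopes, crossed random effects and GEE-style robust variances
  are out of scope.

## A short worked example

```{r, eval = FALSE}
library(climmed)

cfg <- generator_config(n_individuals = 16000, seed = 1)
sim <- simulate_cohort(cfg)

path <- assemble_path_model(sim$cohort, "overweight", quadrature_points = 7)
decompose_effects(path)

boot <- bootstrap_effects(sim$cohort, "overweight",
                          n_reps = 1000, resample_size = 10000, seed = 2)
bootstrap_table(boot)
```

The same workflow, end to end with all tables written to disk, is
`run_pipeline()`; see `?run_pipeline` for the configuration keys.
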