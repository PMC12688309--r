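# climmed

Parallel multiple mediation of climate effects on overweight.

`climmed` is an R package for epidemiologists studying how ambient
temperature relates to overweight and obesity in clustered (province-level)
survey data, and how much of that relationship is carried by behaviour. It
implements a multilevel parallel multiple-mediator analysis with two
mediators operating side by side — adequate fruit/vegetable consumption
(M1, binary) and physical-activity level (M2, low/moderate/high, giving
two pathways) — together with a calibrated synthetic-cohort generator so
the whole pipeline is testable without access to restricted survey
microdata.

## The model

Three structural equations on the log-odds scale, adjusted for sex, age
and education:

```
logit P(M1 = 1)                   = alpha_1  + a1  X + covariates
log  P(M2 = k) / P(M2 = low)      = alpha_2k + a2k X + covariates      k in {moderate, high}
logit P(Y = 1)                    = alpha_y  + c X + b1 M1 + b21 [M2 = moderate]
                                      + b22 [M2 = high] + covariates + u_province
```

with `u_province ~ N(0, sigma^2)` a provincial random intercept integrated
out by adaptive Gauss–Hermite quadrature. Effects are decomposed as

* direct effect `c`;
* specific indirect effects `a1 b1`, `a21 b21`, `a22 b22`
  (product of coefficients);
* per-path total effects `c + a b`;
* raw differences `a1 b1 − a2i b2i` comparing mediator importance,

with percentile-bootstrap confidence intervals (resample rows with
replacement, refit all three equations, recompute every estimand; a
difference is declared when the 95% interval excludes zero).

## Worked example

```r
library(climmed)

## published coefficients in, decomposition out
p <- list(a1 = 0.020, a21 = -0.015, a22 = -0.059,
          b1 = 0.025, b21 = -0.168, b22 = -0.362, c = -0.019)
class(p) <- "path_coefficients"
decompose_effects(p)
#> Effect decomposition (log-odds scale)
#>   direct (c): -0.0190
#>   indirect:
#>     m1        0.0005
#>     m21       0.0025
#>     m22       0.0214
#>   total (direct + path):
#>     m1        -0.0185
#>     m21       -0.0165
#>     m22       0.0024
#>   raw differences:
#>     m1_vs_m21 -0.0020
#>     m1_vs_m22 -0.0209
```

The direct effect of temperature on overweight is negative (−0.019
log-odds per degree C) while the high-physical-activity indirect effect is
positive (+0.021): warmer provinces show less high-level activity
(a22 < 0), and high activity protects against overweight (b22 < 0), so the
pathway pushes overweight up — an *inconsistent mediation* in which the
indirect pathways counteract the direct effect (|c + a22 b22| = 0.002 <
|c|).

The same quantities estimated from a synthetic cohort, with bootstrap
inference:

```r
cfg  <- generator_config(n_individuals = 8000, seed = 1)   # defaults = published coefficients
sim  <- simulate_cohort(cfg)
path <- assemble_path_model(sim$cohort, "overweight", quadrature_points = 7)
path
#> Parallel mediation path coefficients (overweight, n = 7793, 207 dropped)
#>     a1    a21    a22     b1    b21    b22      c sigma2
#>  0.015 -0.020 -0.060  0.040 -0.197 -0.385 -0.026  0.037

boot <- bootstrap_effects(sim$cohort, "overweight",
                          n_reps = 400, resample_size = 4000, seed = 2)
bootstrap_table(boot)[c("direct", "indirect_m22", "raw_diff_m1_m22"), ]
#>                        estimand  estimate boot_se    ci_low  ci_high zero_excluded
#> direct                   direct -0.026733 0.00650 -0.038913 -0.01432          TRUE
#> indirect_m22       indirect_m22  0.023501 0.00635  0.012322  0.03548          TRUE
#> raw_diff_m1_m22 raw_diff_m1_m22 -0.022940 0.00679 -0.036285 -0.01022          TRUE
```

At n = 8,000 the recovered coefficients sit within sampling error of the
generating values; the high-physical-activity indirect effect (0.0235,
95% CI 0.012–0.035) dominates the fruit/vegetable pathway, and the raw
difference between the two excludes zero.

An end-to-end run (simulate → descriptives → model ladder with AIC/BIC →
mediation → bootstrap → manifest) is one call:

```r
run_pipeline(list(outcome = "overweight", seed = 1, out_dir = "out",
                  generator = list(n_individuals = 5000),
                  bootstrap = list(n_reps = 200, resample_size = 2000)))
```

A thin CLI over the same functions ships at `inst/cli/climmed.R`
(`simulate`, `describe`, `fit`, `mediate`, `bootstrap`, `run`).

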