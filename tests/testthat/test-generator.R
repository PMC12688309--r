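test_that("null config produces 50% outcomes and equal activity shares", {
  cfg <- null_config(n = 200000L, seed = 2L)
  co <- simulate_cohort(cfg)$cohort
  se_half <- sqrt(0.25 / cfg$n_individuals)
  se_third <- sqrt((1 / 3) * (2 / 3) / cfg$n_individuals)
  expect_lt(abs(mean(co$overweight == "yes") - 0.5), 3 * se_half)
  expect_lt(abs(mean(co$obesity == "yes") - 0.5), 3 * se_half)
  expect_lt(abs(mean(co$fv_adequate == "yes") - 0.5), 3 * se_half)
  for (lv in c("low", "moderate", "high"))
    expect_lt(abs(mean(co$pa_level == lv) - 1 / 3), 3 * se_third)
})

test_that("generation is bit-reproducible and respects the schema", {
  cfg <- generator_config(n_individuals = 2000L, seed = 17L)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1, s2)
  co <- s1$cohort
  expect_true(all(co$province_id %in% s1$provinces$province_id))
  # temperature constant within every province
  spread <- tapply(co$mean_temp_c, co$province_id, function(x) diff(range(x)))
  expect_true(all(spread == 0))
  expect_false(anyNA(co$pa_level))
})

test_that("missingness in M1 is binomial-consistent and only in M1", {
  cfg <- generator_config(n_individuals = 50000L, seed = 9L)
  co <- simulate_cohort(cfg)$cohort
  p <- cfg$missing_m1_prob
  se <- sqrt(p * (1 - p) / nrow(co))
  expect_lt(abs(mean(is.na(co$fv_adequate)) - p), 4 * se)
  expect_false(anyNA(co[setdiff(names(co), "fv_adequate")]))
})

test_that("negative temperature path forces high activity to fall with warmth", {
  cfg <- generator_config(n_individuals = 200000L, seed = 4L)
  co <- simulate_cohort(cfg)$cohort
  tert <- cut(co$mean_temp_c,
              quantile(unique(co$mean_temp_c), c(0, 1/3, 2/3, 1)),
              include.lowest = TRUE)
  share <- tapply(co$pa_level == "high", tert, mean)
  expect_true(all(diff(share) < 0))
})

test_that("empirical prevalences match the quadrature oracle", {
  cfg <- generator_config(n_individuals = 200000L, seed = 6L)
  co <- simulate_cohort(cfg)$cohort
  n <- nrow(co)
  checks <- list(
    m1 = mean(co$fv_adequate == "yes", na.rm = TRUE),
    pa_moderate = mean(co$pa_level == "moderate"),
    pa_high = mean(co$pa_level == "high"),
    overweight = mean(co$overweight == "yes"),
    obesity = mean(co$obesity == "yes"))
  for (tg in names(checks)) {
    se <- prevalence_total_se(cfg, tg, n)
    expect_lt(abs(checks[[tg]] - marginal_prevalence(cfg, tg)), 4 * se)
  }
})

test_that("marginal_prevalence handles degenerate and intercept-only configs", {
  cfg0 <- null_config()
  expect_equal(marginal_prevalence(cfg0, "overweight"), 0.5, tolerance = 1e-12)
  expect_equal(marginal_prevalence(cfg0, "pa_moderate"), 1 / 3, tolerance = 1e-12)
  cfg <- null_config()
  cfg$y_intercept <- qlogis(0.679)
  expect_equal(marginal_prevalence(cfg, "overweight"), 0.679, tolerance = 1e-10)
})

test_that("a random intercept attenuates the marginal prevalence", {
  cfg <- null_config()
  cfg$y_intercept <- qlogis(0.679)
  cfg$province_variance <- 0.026
  p <- marginal_prevalence(cfg, "overweight")
  expect_lt(p, 0.679)
  # brute-force Monte Carlo oracle for E[plogis(logit(0.679) + b)]
  set.seed(123)
  draws <- plogis(qlogis(0.679) + rnorm(1e6, 0, sqrt(0.026)))
  mc <- mean(draws)
  mc_se <- sd(draws) / sqrt(1e6)
  expect_lt(abs(p - mc), 3 * mc_se)
})

test_that("marginal_prevalence rejects unknown targets", {
  expect_error(marginal_prevalence(null_config(), "bmi"), "unknown target")
})

test_that("intercept calibration hits its targets and is idempotent", {
  cfg0 <- null_config()
  cal <- calibrate_intercepts(cfg0, list(overweight = 0.679))
  expect_equal(cal$y_intercept, qlogis(0.679), tolerance = 1e-6)
  cal5 <- calibrate_intercepts(cfg0, list(overweight = 0.5))
  expect_equal(cal5$y_intercept, 0, tolerance = 1e-8)

  cfg <- generator_config()   # default path: reference slopes + calibration
  tg <- default_prevalence_targets()
  expect_lt(abs(marginal_prevalence(cfg, "overweight") - tg$overweight), 1e-6)
  expect_lt(abs(marginal_prevalence(cfg, "m1") - tg$m1), 1e-6)
  expect_lt(abs(marginal_prevalence(cfg, "pa_moderate") - tg$pa[["moderate"]]), 1e-6)
  expect_lt(abs(marginal_prevalence(cfg, "pa_high") - tg$pa[["high"]]), 1e-6)
  expect_lt(abs(marginal_prevalence(cfg, "obesity") - tg$obesity), 1e-6)
  again <- calibrate_intercepts(cfg)
  expect_equal(again$y_intercept, cfg$y_intercept, tolerance = 1e-8)
  expect_equal(again$m2_intercepts, cfg$m2_intercepts, tolerance = 1e-8)
})

test_that("unattainable calibration targets raise a calibration error", {
  expect_error(calibrate_intercepts(null_config(), list(overweight = 1)),
               "calibration failure")
})

test_that("config validation names the offending field", {
  expect_error(generator_config(education_probs = c(
    university = 0.3, incomplete_primary = 0.3,
    incomplete_secondary = 0.3, complete_secondary = 0.2)),
    "education_probs")
  expect_error(generator_config(province_variance = -1), "province_variance")
  expect_error(generator_config(missing_m1_prob = 1.5), "missing_m1_prob")
  expect_error(generator_config(temp_min = 30, temp_max = 10), "temp_min")
  expect_error(generator_config(age_min = 90, age_max = 20), "age_min")
})
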