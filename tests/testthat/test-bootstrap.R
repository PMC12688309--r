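test_that("bootstrap is deterministic given data and seed", {
  sim <- simulate_cohort(generator_config(n_individuals = 4000L, seed = 21L))
  b1 <- bootstrap_effects(sim$cohort, "overweight",
                          estimands = c("direct", "indirect_m22"),
                          n_reps = 60, resample_size = 1500, seed = 5)
  b2 <- bootstrap_effects(sim$cohort, "overweight",
                          estimands = c("direct", "indirect_m22"),
                          n_reps = 60, resample_size = 1500, seed = 5)
  expect_identical(b1$direct$ci, b2$direct$ci)
  expect_identical(b1$indirect_m22$replicates, b2$indirect_m22$replicates)
  b3 <- bootstrap_effects(sim$cohort, "overweight",
                          estimands = "direct",
                          n_reps = 60, resample_size = 1500, seed = 6)
  expect_false(identical(b1$direct$ci, b3$direct$ci))
})

test_that("CI endpoints are order statistics and bracket the estimate sanely", {
  sim <- simulate_cohort(generator_config(n_individuals = 4000L, seed = 22L))
  b <- bootstrap_effects(sim$cohort, "overweight", estimands = "direct",
                         n_reps = 120, resample_size = 2000, seed = 3)
  r <- b$direct
  expect_lte(r$ci[1], r$ci[2])
  expect_true(all(r$ci %in% r$replicates))
  expect_equal(r$boot_se, sd(r$replicates))
  expect_equal(length(r$replicates) + r$n_failed_replicates, r$n_reps)
})

test_that("a true-null indirect effect gets a CI containing zero", {
  cfg <- generator_config(n_individuals = 5000L, m1_temp = 0, y_m1 = 0,
                          seed = 33L)
  sim <- simulate_cohort(cfg)
  b <- bootstrap_effects(sim$cohort, "overweight", estimands = "indirect_m1",
                         n_reps = 500, seed = 7)
  ci <- b$indirect_m1$ci
  expect_lte(ci[1], 0)
  expect_gte(ci[2], 0)
})

test_that("bootstrap SE stabilises as replicates grow", {
  sim <- simulate_cohort(generator_config(n_individuals = 1500L, seed = 44L))
  b2k <- bootstrap_effects(sim$cohort, "overweight", estimands = "direct",
                           n_reps = 2000, seed = 11)
  b5k <- bootstrap_effects(sim$cohort, "overweight", estimands = "direct",
                           n_reps = 5000, seed = 11)
  rel <- abs(b5k$direct$boot_se - b2k$direct$boot_se) / b2k$direct$boot_se
  expect_lt(rel, 0.10)
})

test_that("failed replicates are counted, warned about, and fatal in strict mode", {
  cfg <- generator_config(n_individuals = 1200L, seed = 66L)
  sim <- simulate_cohort(cfg)
  co <- sim$cohort
  # make the high-activity category so rare that tiny resamples often miss it
  co$pa_level[co$pa_level == "high"][-(1:12)] <- "low"
  expect_warning(
    b <- bootstrap_effects(co, "overweight", estimands = "indirect_m22",
                           n_reps = 50, resample_size = 60, seed = 2),
    "failed")
  expect_gt(b$indirect_m22$n_failed_replicates, 0)
  expect_error(
    suppressWarnings(
      bootstrap_effects(co, "overweight", estimands = "indirect_m22",
                        n_reps = 50, resample_size = 60, seed = 2,
                        strict = TRUE)),
    "failed")
})

test_that("invalid bootstrap arguments are rejected", {
  sim <- simulate_cohort(generator_config(n_individuals = 500L, seed = 1L))
  expect_error(bootstrap_effects(sim$cohort, "overweight",
                                 estimands = "magic", n_reps = 10),
               "unknown estimand")
  expect_error(bootstrap_effects(sim$cohort, "overweight", n_reps = 10,
                                 resample_size = 10000),
               "exceeds")
})
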