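published_paths <- function(outcome = "overweight") {
  # fitted coefficients of the published parallel-mediator models
  if (outcome == "overweight")
    list(a1 = 0.020, a21 = -0.015, a22 = -0.059,
         b1 = 0.025, b21 = -0.168, b22 = -0.362, c = -0.019)
  else
    list(a1 = 0.020, a21 = -0.015, a22 = -0.059,
         b1 = 0.018, b21 = -0.234, b22 = -0.413, c = -0.021)
}

as_path <- function(p) structure(p, class = "path_coefficients")

test_that("effect decomposition reproduces the published products", {
  dec <- decompose_effects(as_path(published_paths("overweight")))
  expect_equal(unname(dec$indirect[["m1"]]), 0.0005, tolerance = 1e-12)
  expect_equal(round(unname(dec$indirect[["m22"]]), 3), 0.021)
  expect_equal(round(unname(dec$total[["m22"]]), 3), 0.002)
  dec_ob <- decompose_effects(as_path(published_paths("obesity")))
  expect_equal(round(unname(dec_ob$indirect[["m22"]]), 3), 0.024)
})

test_that("a null path contributes no indirect effect and total equals direct", {
  p <- published_paths()
  p$a1 <- 0
  dec <- decompose_effects(as_path(p))
  expect_identical(unname(dec$indirect[["m1"]]), 0)
  expect_identical(unname(dec$total[["m1"]]), dec$direct)
})

test_that("decomposition identities hold bit-exactly on random coefficients", {
  set.seed(99)
  for (i in 1:200) {
    p <- as_path(list(a1 = rnorm(1), a21 = rnorm(1), a22 = rnorm(1),
                      b1 = rnorm(1), b21 = rnorm(1), b22 = rnorm(1),
                      c = rnorm(1)))
    dec <- decompose_effects(p)
    expect_identical(unname(dec$indirect),
                     c(p$a1 * p$b1, p$a21 * p$b21, p$a22 * p$b22))
    expect_identical(unname(dec$total), unname(dec$direct + dec$indirect))
    expect_identical(unname(dec$raw_diff),
                     c(dec$indirect[["m1"]] - dec$indirect[["m21"]],
                       dec$indirect[["m1"]] - dec$indirect[["m22"]]))
  }
})

test_that("raw_difference is signed, antisymmetric, with an absolute mode", {
  dec <- decompose_effects(as_path(published_paths()))
  d12 <- raw_difference(dec, "m1", "m22")
  expect_equal(d12, 0.0005 - (-0.059) * (-0.362), tolerance = 1e-12)
  expect_equal(raw_difference(dec, "m22", "m1"), -d12)
  expect_equal(raw_difference(dec, "m1", "m22", mode = "absolute"), abs(d12))
  # published magnitude: |0.0005 - 0.021358| ~ 0.020 within print rounding
  expect_equal(round(abs(d12), 2), 0.02)
  expect_identical(raw_difference(dec, "m21", "m21"), 0)
  expect_error(raw_difference(dec, "m1", "m99"), "unknown path")
})

test_that("zero-exclusion rule matches the published interval calls", {
  expect_true(zero_excluded(list(ci = c(0.001, 0.030))))
  expect_false(zero_excluded(list(ci = c(-0.002, 0.006))))
  expect_false(zero_excluded(list(ci = c(0, 0.5))))   # closed endpoint
  expect_true(zero_excluded(list(ci = c(-0.5, -0.1))))
  expect_error(zero_excluded(list(ci = c(1, -1))), "valid")
})

test_that("path assembly recovers generating coefficients and is deterministic", {
  sim <- default_sim()
  path <- assemble_path_model(sim$cohort, "overweight", quadrature_points = 1)
  expect_equal(path$n_used + path$n_dropped, nrow(sim$cohort))
  se_a22 <- path$fits$m2$standard_errors[["high:mean_temp_c"]]
  expect_lt(abs(path$a22 - (-0.059)), 3 * se_a22)
  se_b22 <- path$fits$y$standard_errors[["pa_levelhigh"]]
  expect_lt(abs(path$b22 - (-0.362)), 3 * se_b22)
  path2 <- assemble_path_model(sim$cohort, "overweight", quadrature_points = 1)
  expect_identical(path[c("a1", "a21", "a22", "b1", "b21", "b22", "c", "sigma2")],
                   path2[c("a1", "a21", "a22", "b1", "b21", "b22", "c", "sigma2")])
})

test_that("a generating null X->M1 path is recovered as null", {
  cfg <- generator_config(n_individuals = 20000L, m1_temp = 0, seed = 55L)
  sim <- simulate_cohort(cfg)
  path <- assemble_path_model(sim$cohort, "overweight", quadrature_points = 0)
  expect_lt(abs(path$a1), 3 * path$fits$m1$standard_errors[["mean_temp_c"]])
})

test_that("equation failures are labelled with the failing equation", {
  sim <- default_sim()
  co <- sim$cohort[1:500, ]
  co$fv_adequate <- factor("yes", levels = c("no", "yes"))
  expect_error(assemble_path_model(co, "overweight", quadrature_points = 0),
               "M1 equation")
})
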