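test_that("logistic slope on a 2x2 expansion equals the closed-form log odds ratio", {
  counts <- enfr_table1_counts()
  d <- expand_table1(counts, "sex", levels = c("male", "female"))
  fit <- fit_logistic(outcome ~ sex, d)
  closed <- log((6170 * 1988) / (3280 * 4972))
  expect_equal(unname(fit$coefficients[["sexfemale"]]), closed,
               tolerance = 1e-8)
  expect_lt(fit$max_abs_gradient, 1e-6)
  # intercept is the reference-group log odds
  expect_equal(unname(fit$coefficients[["(Intercept)"]]), log(4972 / 1988),
               tolerance = 1e-8)
})

test_that("degenerate and separated logistic problems fail loudly", {
  d <- data.frame(y = rep(1, 50), x = rnorm(50))
  expect_error(fit_logistic(y ~ x, d), "degenerate response")
  d2 <- data.frame(y = rep(c(0, 1), each = 25),
                   x = c(seq(0, 1, length.out = 25), seq(2, 3, length.out = 25)))
  expect_error(fit_logistic(y ~ x, d2), "separation")
  d3 <- data.frame(y = rbinom(60, 1, 0.5), x = rnorm(60))
  d3$x2 <- 2 * d3$x
  expect_error(fit_logistic(y ~ x + x2, d3), "rank-deficient")
})

test_that("logistic regression recovers a known slope from simulated data", {
  set.seed(31)
  n <- 100000
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.4 + 0.25 * x))
  fit <- fit_logistic(y ~ x, data.frame(y = y, x = x))
  expect_lt(abs(fit$coefficients[["x"]] - 0.25),
            3 * fit$standard_errors[["x"]])
})

test_that("loglik never decreases when a predictor is added and is scale-invariant", {
  co <- default_sim()$cohort
  co <- co[!is.na(co$fv_adequate), ][1:5000, ]
  f0 <- fit_logistic(overweight ~ mean_temp_c, co)
  f1 <- fit_logistic(overweight ~ mean_temp_c + sex, co)
  expect_gte(f1$loglik, f0$loglik)
  co$temp10 <- co$mean_temp_c * 10
  f10 <- fit_logistic(overweight ~ temp10, co)
  expect_equal(f10$loglik, f0$loglik, tolerance = 1e-8)
  expect_equal(unname(f10$coefficients[["temp10"]]),
               unname(f0$coefficients[["mean_temp_c"]]) / 10,
               tolerance = 1e-8)
})

test_that("two-level multinomial reduces exactly to binary logistic", {
  co <- default_sim()$cohort[1:8000, ]
  co$pa2 <- factor(ifelse(co$pa_level == "low", "low", "active"),
                   levels = c("low", "active"))
  fm <- fit_multinomial(pa2 ~ mean_temp_c + sex + age, co)
  fb <- fit_logistic(I(pa2 == "active") ~ mean_temp_c + sex + age, co)
  expect_equal(unname(fm$coefficients), unname(fb$coefficients),
               tolerance = 1e-8)
  expect_equal(fm$loglik, fb$loglik, tolerance = 1e-8)
})

test_that("saturated multinomial equals log relative-frequency ratios", {
  co <- default_sim()$cohort[1:10000, ]
  fm <- fit_multinomial(pa_level ~ sex, co, reference = "low")
  tab <- table(co$sex, co$pa_level)
  # intercept: log(n_k / n_low) among the reference sex; slope: difference
  # of those log ratios between sexes (closed-form saturated-model MLE)
  for (k in c("moderate", "high")) {
    b0 <- log(tab["male", k] / tab["male", "low"])
    b1 <- log(tab["female", k] / tab["female", "low"]) - b0
    expect_equal(unname(fm$coefficients[[paste0(k, ":(Intercept)")]]), b0,
                 tolerance = 1e-7)
    expect_equal(unname(fm$coefficients[[paste0(k, ":sexfemale")]]), b1,
                 tolerance = 1e-7)
  }
})

test_that("relabelling non-reference categories permutes blocks, loglik unchanged", {
  co <- default_sim()$cohort[1:6000, ]
  f1 <- fit_multinomial(pa_level ~ mean_temp_c, co, reference = "low")
  co$pa_swap <- factor(co$pa_level, levels = c("low", "high", "moderate"))
  f2 <- fit_multinomial(pa_swap ~ mean_temp_c, co, reference = "low")
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
  expect_equal(unname(f1$coefficients[["high:mean_temp_c"]]),
               unname(f2$coefficients[["high:mean_temp_c"]]),
               tolerance = 1e-8)
  expect_equal(unname(f1$coefficients[["moderate:(Intercept)"]]),
               unname(f2$coefficients[["moderate:(Intercept)"]]),
               tolerance = 1e-8)
})

test_that("a declared but unobserved category is rejected", {
  co <- default_sim()$cohort[1:1000, ]
  co$pa4 <- factor(as.character(co$pa_level),
                   levels = c("low", "moderate", "high", "extreme"))
  expect_error(fit_multinomial(pa4 ~ mean_temp_c, co), "absent from data")
  expect_error(fit_multinomial(pa_level ~ mean_temp_c, co, reference = "xxx"),
               "absent from data")
})

test_that("information criteria follow their definitions", {
  expect_equal(unname(information_criteria(0, 0, 10)), c(0, 0))
  ic <- information_criteria(-100, 0, 50)
  expect_equal(unname(ic), c(200, 200))
  ic2 <- information_criteria(-1234.5, 7, 321)
  expect_equal(ic2[["aic"]], 2 * 7 + 2 * 1234.5)
  expect_equal(ic2[["bic"]], 7 * log(321) + 2 * 1234.5)
})

test_that("random-intercept fit constrained to sigma^2 = 0 matches plain logistic", {
  co <- default_sim()$cohort[1:8000, ]
  fz <- fit_logistic_ri(overweight ~ mean_temp_c + sex, co, "province_id",
                        quadrature_points = 7, constrain_zero = TRUE)
  fg <- fit_logistic(overweight ~ mean_temp_c + sex, co)
  expect_equal(fz$loglik, fg$loglik, tolerance = 1e-8)
  expect_equal(fz$variance_component[["sigma2"]], 0)
})

test_that("random-intercept fit recovers a known variance component", {
  set.seed(77)
  n_cl <- 200; m <- 200
  cl <- rep(seq_len(n_cl), each = m)
  b <- rnorm(n_cl, 0, sqrt(0.026))
  x <- rnorm(n_cl * m)
  y <- rbinom(n_cl * m, 1, plogis(0.3 + 0.2 * x + b[cl]))
  d <- data.frame(y = y, x = x, g = cl)
  fit <- fit_logistic_ri(y ~ x, d, "g", quadrature_points = 7)
  s2 <- fit$variance_component[["sigma2"]]
  se <- fit$variance_component[["se"]]
  expect_false(is.na(se))
  expect_lt(abs(s2 - 0.026), 3 * se)
  # shuffling cluster labels destroys the between-cluster variance
  d$g_perm <- sample(d$g)
  fperm <- fit_logistic_ri(y ~ x, d, "g_perm", quadrature_points = 7,
                           variance_se = FALSE)
  # permutation removes all between-cluster structure: the estimate drops
  # toward the boundary, far below the generating 0.026
  expect_lt(fperm$variance_component[["sigma2"]], 0.026 / 2)
  expect_lt(fperm$variance_component[["sigma2"]], s2)
})

test_that("loglik is stable when the quadrature order doubles", {
  co <- default_sim()$cohort[1:10000, ]
  f7 <- fit_logistic_ri(overweight ~ mean_temp_c + sex, co, "province_id",
                        quadrature_points = 7, variance_se = FALSE)
  f14 <- fit_logistic_ri(overweight ~ mean_temp_c + sex, co, "province_id",
                         quadrature_points = 14, variance_se = FALSE)
  expect_lt(abs(f7$loglik - f14$loglik), 1e-6)
})

test_that("a single cluster leaves the variance unidentified", {
  co <- default_sim()$cohort
  co1 <- co[co$province_id == 1, ]
  expect_error(fit_logistic_ri(overweight ~ mean_temp_c, co1, "province_id"),
               "unidentified")
})

test_that("the model ladder orders information criteria sensibly", {
  co <- default_sim()$cohort[1:8000, ]
  lad <- fit_model_ladder(co, "overweight", quadrature_points = 1)
  expect_equal(lad$table$model, c("model1", "model2", "model3"))
  # covariates carry real signal in the generator, so model 2 must improve
  expect_lt(lad$table$aic[2], lad$table$aic[1])
  expect_equal(lad$table$aic, 2 * lad$table$n_params - 2 * lad$table$loglik)
})
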