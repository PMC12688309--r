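# Deterministic population-level prevalences implied by a generator config,
# and root-finding calibration of the equation intercepts against target
# marginals. No sampling is involved: covariates are enumerated (province,
# sex, education) or integrated by Gauss-Legendre quadrature (age), the
# province random intercept by Gauss-Hermite quadrature, and the mediators by
# summing over their six joint states.

province_table_for <- function(config) {
  make_province_table(config$n_provinces, config$temp_min, config$temp_max,
                      mode = config$temp_mode, seed = config$seed)
}

# covariate enumeration grid with integration weights summing to 1
covariate_grid <- function(config, n_age_nodes = 24L) {
  prov <- province_table_for(config)
  gl <- pracma::gaussLegendre(n_age_nodes, config$age_min, config$age_max)
  z <- stats::pnorm(config$age_max, config$age_mean, config$age_sd) -
       stats::pnorm(config$age_min, config$age_mean, config$age_sd)
  age_w <- gl$w * stats::dnorm(gl$x, config$age_mean, config$age_sd) / z
  age_w <- age_w / sum(age_w)          # absorb residual quadrature error
  grid <- expand.grid(prov_i = seq_len(nrow(prov)),
                      female = c(0, 1),
                      edu = .education_levels,
                      age_i = seq_len(n_age_nodes),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$temp <- prov$mean_temp_c[grid$prov_i]
  grid$age <- gl$x[grid$age_i]
  pf <- config$sex_female_prob
  grid$w <- (1 / nrow(prov)) *
    ifelse(grid$female == 1, pf, 1 - pf) *
    config$education_probs[grid$edu] *
    age_w[grid$age_i]
  grid
}

covariate_lp <- function(effects, grid) {
  effects[["female"]] * grid$female +
    effects[["age"]] * grid$age +
    effects[["edu_incomplete_primary"]] * (grid$edu == "incomplete_primary") +
    effects[["edu_incomplete_secondary"]] * (grid$edu == "incomplete_secondary") +
    effects[["edu_complete_secondary"]] * (grid$edu == "complete_secondary")
}

# mediator probabilities for each grid row at random-intercept value b
mediator_probs <- function(config, grid, b = 0) {
  bm <- if (config$mediator_random_intercept) b else 0
  p_m1 <- stats::plogis(config$m1_intercept + config$m1_temp * grid$temp +
                          covariate_lp(config$m1_covariate_effects, grid) + bm)
  eta_mod <- config$m2_intercepts[["moderate"]] +
    config$m2_temp[["moderate"]] * grid$temp +
    covariate_lp(config$m2_covariate_effects$moderate, grid) + bm
  eta_high <- config$m2_intercepts[["high"]] +
    config$m2_temp[["high"]] * grid$temp +
    covariate_lp(config$m2_covariate_effects$high, grid) + bm
  denom <- 1 + exp(eta_mod) + exp(eta_high)
  list(m1 = p_m1, pa_moderate = exp(eta_mod) / denom,
       pa_high = exp(eta_high) / denom)
}

outcome_coefs <- function(config, outcome) {
  if (outcome == "overweight")
    list(intercept = config$y_intercept, temp = config$y_temp,
         m1 = config$y_m1, m2_moderate = config$y_m2_moderate,
         m2_high = config$y_m2_high, cov = config$y_covariate_effects)
  else
    list(intercept = config$obesity_intercept, temp = config$obesity_temp,
         m1 = config$obesity_m1, m2_moderate = config$obesity_m2_moderate,
         m2_high = config$obesity_m2_high, cov = config$obesity_covariate_effects)
}

#' Population prevalence implied by a generator configuration
#'
#' Computes, without any sampling, the marginal prevalence of a mediator or
#' outcome implied by the structural equations of a [generator_config()]:
#' the covariate distributions are enumerated or integrated by quadrature,
#' the province random intercept by Gauss-Hermite quadrature, and the
#' mediators by summation over their joint states. Serves as the exact
#' oracle against which the stochastic generator is validated, and as the
#' objective of [calibrate_intercepts()].
#'
#' @param config a [generator_config()].
#' @param target one of `"m1"` (adequate fruit/vegetable consumption),
#'   `"pa_moderate"`, `"pa_high"`, `"overweight"`, `"obesity"`.
#' @param n_age_nodes,n_re_nodes quadrature sizes (age; random intercept).
#' @return A single probability.
#' @examples
#' cfg <- generator_config(calibrate = FALSE)
#' marginal_prevalence(cfg, "pa_high")
#' @export
marginal_prevalence <- function(config, target,
                                n_age_nodes = 24L, n_re_nodes = 21L) {
  validate_generator_config(config)
  targets <- c("m1", "pa_moderate", "pa_high", "overweight", "obesity")
  if (!is.character(target) || length(target) != 1L || !(target %in% targets))
    stop_invalid("unknown target '%s'; expected one of: %s",
                 as.character(target)[1], paste(targets, collapse = ", "))
  grid <- covariate_grid(config, n_age_nodes)
  gh <- gauss_hermite_normal(n_re_nodes, 0, config$province_variance)

  if (target %in% c("m1", "pa_moderate", "pa_high")) {
    if (!config$mediator_random_intercept) {
      mp <- mediator_probs(config, grid, 0)
      return(sum(grid$w * mp[[target]]))
    }
    acc <- 0
    for (k in seq_along(gh$nodes)) {
      mp <- mediator_probs(config, grid, gh$nodes[k])
      acc <- acc + gh$weights[k] * sum(grid$w * mp[[target]])
    }
    return(acc)
  }

  oc <- outcome_coefs(config, target)
  base_lp <- oc$intercept + oc$temp * grid$temp + covariate_lp(oc$cov, grid)
  acc <- 0
  for (k in seq_along(gh$nodes)) {
    b <- gh$nodes[k]
    mp <- mediator_probs(config, grid, b)
    p_low <- 1 - mp$pa_moderate - mp$pa_high
    p_y <- 0
    for (m1 in c(0, 1)) {
      w_m1 <- if (m1 == 1) mp$m1 else 1 - mp$m1
      for (m2 in .pa_levels) {
        w_m2 <- switch(m2, low = p_low, moderate = mp$pa_moderate,
                       high = mp$pa_high)
        shift <- m1 * oc$m1 +
          (m2 == "moderate") * oc$m2_moderate + (m2 == "high") * oc$m2_high
        p_y <- p_y + w_m1 * w_m2 * stats::plogis(base_lp + shift + b)
      }
    }
    acc <- acc + gh$weights[k] * sum(grid$w * p_y)
  }
  acc
}

#' Calibrate equation intercepts to target marginal prevalences
#'
#' The published structural coefficients fix every slope of the generator
#' but not the intercepts. This routine root-finds the intercepts so that
#' the implied marginal prevalences ([marginal_prevalence()]) hit the
#' requested targets: one-dimensional bisection/Brent for the binary
#' equations (M1, overweight, obesity) and a damped Newton iteration with a
#' numerical Jacobian for the two multinomial intercepts jointly. Mediator
#' equations are calibrated before the outcome equations, which depend on
#' them. Calibration is deterministic and idempotent.
#'
#' @param config a [generator_config()].
#' @param targets named list; any subset of `m1` (probability), `pa` (named
#'   vector with `moderate` and `high` shares), `overweight`, `obesity`.
#'   Omitted elements leave the corresponding intercepts untouched.
#' @param tol required accuracy on each achieved prevalence.
#' @return The configuration with calibrated intercepts.
#' @export
calibrate_intercepts <- function(config, targets = default_prevalence_targets(),
                                 tol = 1e-6) {
  validate_generator_config(config)
  solve1 <- function(cfg, field, target, what) {
    assert_prob(target, paste0("targets$", what))
    if (target <= 0 || target >= 1)
      stop_invalid("calibration failure for '%s': target must lie strictly inside (0, 1)",
                   what)
    f <- function(a) { cfg[[field]] <- a; marginal_prevalence(cfg, what) - target }
    if (f(-40) > 0 || f(40) < 0)
      stop_invalid("calibration failure for '%s': target %g is not attainable (root not bracketed)",
                   what, target)
    r <- tryCatch(stats::uniroot(f, c(-40, 40), tol = 1e-12),
                  error = function(e)
                    stop_invalid("calibration failure for '%s': %s", what,
                                 conditionMessage(e)))
    cfg[[field]] <- r$root
    if (abs(marginal_prevalence(cfg, what) - target) > tol)
      stop_invalid("calibration failure for '%s': target %g not attained", what,
                   target)
    cfg
  }
  if (!is.null(targets$m1))
    config <- solve1(config, "m1_intercept", targets$m1, "m1")
  if (!is.null(targets$pa)) {
    tg <- targets$pa
    if (!setequal(names(tg), c("moderate", "high")) || any(tg <= 0) ||
        sum(tg) >= 1)
      stop_invalid("targets$pa must be named shares (moderate, high) with sum < 1")
    shares <- function(a) {
      cfg <- config; cfg$m2_intercepts <- c(moderate = a[1], high = a[2])
      c(marginal_prevalence(cfg, "pa_moderate") - tg[["moderate"]],
        marginal_prevalence(cfg, "pa_high") - tg[["high"]])
    }
    a <- unname(config$m2_intercepts[c("moderate", "high")])
    ok <- FALSE
    for (it in 1:60) {
      fv <- shares(a)
      if (max(abs(fv)) < tol * 1e-3) { ok <- TRUE; break }
      h <- 1e-6
      J <- cbind((shares(a + c(h, 0)) - fv) / h, (shares(a + c(0, h)) - fv) / h)
      step <- tryCatch(solve(J, fv), error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step)))
        stop_invalid("calibration failure for 'pa': singular Jacobian")
      step <- pmin(pmax(-step, -4), 4)   # damp large excursions
      a <- a + step
    }
    if (!ok) stop_invalid("calibration failure for 'pa': no convergence")
    config$m2_intercepts <- c(moderate = a[1], high = a[2])
  }
  if (!is.null(targets$overweight))
    config <- solve1(config, "y_intercept", targets$overweight, "overweight")
  if (!is.null(targets$obesity))
    config <- solve1(config, "obesity_intercept", targets$obesity, "obesity")
  config
}
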