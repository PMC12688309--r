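# shared fixtures: configs and cached simulations used across test files

# config with every slope and intercept at zero and no clustering
null_config <- function(n = 1000L, seed = 1L, ...) {
  generator_config(
    n_individuals = n, seed = seed,
    m1_intercept = 0, m1_temp = 0,
    m2_intercepts = c(moderate = 0, high = 0),
    m2_temp = c(moderate = 0, high = 0),
    y_intercept = 0, y_temp = 0, y_m1 = 0, y_m2_moderate = 0, y_m2_high = 0,
    y_covariate_effects = NULL,
    obesity_intercept = 0, obesity_temp = 0, obesity_m1 = 0,
    obesity_m2_moderate = 0, obesity_m2_high = 0,
    obesity_covariate_effects = NULL,
    province_variance = 0, missing_m1_prob = 0,
    calibrate = FALSE, ...)
}

# total standard error of an empirical prevalence under the generator:
# binomial sampling plus the between-province random-intercept component,
# which enters the linear predictor like an intercept shift
prevalence_total_se <- function(config, target, n) {
  p <- marginal_prevalence(config, target)
  h <- 1e-4
  field <- switch(target,
                  m1 = "m1_intercept", overweight = "y_intercept",
                  obesity = "obesity_intercept", NULL)
  s <- 0
  if (!is.null(field) && config$province_variance > 0) {
    up <- config; up[[field]] <- up[[field]] + h
    dn <- config; dn[[field]] <- dn[[field]] - h
    s <- (marginal_prevalence(up, target) - marginal_prevalence(dn, target)) / (2 * h)
  }
  sqrt(p * (1 - p) / n + s^2 * config$province_variance / config$n_provinces)
}

# one medium default cohort shared by estimation/mediation tests
default_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_cohort(generator_config(n_individuals = 30000L,
                                                 seed = 42L))
    cache
  }
})
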