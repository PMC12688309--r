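#' Simulate a synthetic cohort
#'
#' Draws an individual-level cohort with the statistical structure the
#' mediation analysis assumes: individuals are assigned uniformly to
#' provinces carrying a fixed annual mean temperature; sex, age (truncated
#' normal) and education come from configured marginals; fruit/vegetable
#' adequacy (M1) follows a Bernoulli logistic equation, physical-activity
#' level (M2) a three-category multinomial logit versus low, and each binary
#' outcome a Bernoulli logistic equation that includes the realized
#' mediators and a province-level random intercept ~ N(0, sigma^2).
#' Fruit/vegetable values are finally masked to missing completely at
#' random. Every sampling stage draws under its own sub-seed derived from
#' `config$seed`, so the output is bit-reproducible and adding a stage never
#' perturbs earlier draws.
#'
#' @param config a [generator_config()].
#' @return A list with components `provinces` (the province table) and
#'   `cohort` (a `data.frame` with columns `province_id`, `mean_temp_c`,
#'   `sex`, `age`, `education`, `fv_adequate`, `pa_level`, `overweight`,
#'   `obesity`; factor reference levels are male, university, low activity,
#'   inadequate consumption).
#' @examples
#' sim <- simulate_cohort(generator_config(n_individuals = 500,
#'                                         calibrate = FALSE))
#' head(sim$cohort)
#' @export
simulate_cohort <- function(config) {
  validate_generator_config(config)
  n <- config$n_individuals
  seed <- config$seed
  prov <- province_table_for(config)

  prov_i <- with_seed(stage_seed(seed, "province_assign"),
                      sample.int(nrow(prov), n, replace = TRUE))
  temp <- prov$mean_temp_c[prov_i]

  sigma <- sqrt(config$province_variance)
  b_prov <- with_seed(stage_seed(seed, "random_intercept"),
                      stats::rnorm(nrow(prov), 0, sigma))
  b_prov_ob <- with_seed(stage_seed(seed, "obesity_random_intercept"),
                         stats::rnorm(nrow(prov), 0, sigma))
  b <- b_prov[prov_i]
  b_ob <- b_prov_ob[prov_i]

  female <- with_seed(stage_seed(seed, "sex"),
                      stats::rbinom(n, 1L, config$sex_female_prob))
  # inverse-CDF truncated normal, exact given the uniform sub-stream
  lo <- stats::pnorm(config$age_min, config$age_mean, config$age_sd)
  hi <- stats::pnorm(config$age_max, config$age_mean, config$age_sd)
  age <- with_seed(stage_seed(seed, "age"),
    stats::qnorm(stats::runif(n, lo, hi), config$age_mean, config$age_sd))
  education <- with_seed(stage_seed(seed, "education"),
    sample(.education_levels, n, replace = TRUE,
           prob = config$education_probs[.education_levels]))

  grid <- data.frame(temp = temp, female = female, age = age, edu = education)
  bm <- if (config$mediator_random_intercept) b else 0

  lp_m1 <- config$m1_intercept + config$m1_temp * temp +
    covariate_lp(config$m1_covariate_effects, grid) + bm
  m1 <- with_seed(stage_seed(seed, "m1"),
                  stats::rbinom(n, 1L, stats::plogis(lp_m1)))

  eta_mod <- config$m2_intercepts[["moderate"]] +
    config$m2_temp[["moderate"]] * temp +
    covariate_lp(config$m2_covariate_effects$moderate, grid) + bm
  eta_high <- config$m2_intercepts[["high"]] +
    config$m2_temp[["high"]] * temp +
    covariate_lp(config$m2_covariate_effects$high, grid) + bm
  denom <- 1 + exp(eta_mod) + exp(eta_high)
  p_mod <- exp(eta_mod) / denom
  p_high <- exp(eta_high) / denom
  u <- with_seed(stage_seed(seed, "m2"), stats::runif(n))
  pa <- ifelse(u < p_mod, "moderate", ifelse(u < p_mod + p_high, "high", "low"))

  draw_outcome <- function(outcome, stage, b_re) {
    oc <- outcome_coefs(config, outcome)
    lp <- oc$intercept + oc$temp * temp + covariate_lp(oc$cov, grid) +
      oc$m1 * m1 + oc$m2_moderate * (pa == "moderate") +
      oc$m2_high * (pa == "high") + b_re
    with_seed(stage_seed(seed, stage), stats::rbinom(n, 1L, stats::plogis(lp)))
  }
  overweight <- draw_outcome("overweight", "overweight", b)
  obesity <- draw_outcome("obesity", "obesity", b_ob)

  miss <- with_seed(stage_seed(seed, "missing_m1"),
                    stats::rbinom(n, 1L, config$missing_m1_prob)) == 1L
  fv <- factor(ifelse(m1 == 1L, "yes", "no"), levels = c("no", "yes"))
  fv[miss] <- NA

  cohort <- data.frame(
    province_id = prov$province_id[prov_i],
    mean_temp_c = temp,
    sex = factor(ifelse(female == 1L, "female", "male"),
                 levels = c("male", "female")),
    age = age,
    education = factor(education, levels = .education_levels),
    fv_adequate = fv,
    pa_level = factor(pa, levels = .pa_levels),
    overweight = factor(ifelse(overweight == 1L, "yes", "no"),
                        levels = c("no", "yes")),
    obesity = factor(ifelse(obesity == 1L, "yes", "no"),
                     levels = c("no", "yes")))
  list(provinces = prov, cohort = cohort)
}
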