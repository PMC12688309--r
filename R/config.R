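# Generator configuration: structural coefficients, covariate marginals and
# sampling settings for the synthetic-cohort generator.

.covariate_terms <- c("female", "age", "edu_incomplete_primary",
                      "edu_incomplete_secondary", "edu_complete_secondary")

.education_levels <- c("university", "incomplete_primary",
                       "incomplete_secondary", "complete_secondary")

.pa_levels <- c("low", "moderate", "high")

zero_covariate_effects <- function() {
  stats::setNames(numeric(length(.covariate_terms)), .covariate_terms)
}

#' Default marginal prevalence targets for intercept calibration
#'
#' Marginal prevalences of the 2018 Argentine risk-factor survey sample used
#' to pin down the equation intercepts (which the fitted structural
#' coefficients alone do not determine): overweight 67.9%, physical-activity
#' split 47/36/18% (low/moderate/high), adequate fruit/vegetable consumption
#' about 6%, and measured obesity 32.4%.
#'
#' @return A named list with elements `m1`, `pa` (named vector `moderate`,
#'   `high`), `overweight`, `obesity`.
#' @export
default_prevalence_targets <- function() {
  list(m1 = 0.06,
       pa = c(moderate = 0.36, high = 0.18),
       overweight = 0.679,
       obesity = 0.324)
}

#' Construct a synthetic-cohort generator configuration
#'
#' Bundles every quantity the cohort generator needs: sample sizes, the
#' province temperature layout, covariate marginals, and the structural
#' coefficients of the three logistic/multinomial equations (fruit/vegetable
#' adequacy M1, physical-activity level M2 vs low, and the binary outcomes),
#' all on the log-odds scale. Defaults are the fitted coefficients of the
#' parallel multiple-mediator model: a1 = 0.020, (a21, a22) = (-0.015,
#' -0.059), b1 = 0.025, (b21, b22) = (-0.168, -0.362), direct effect
#' c = -0.019 for overweight (and b1 = 0.018, (b21, b22) = (-0.234, -0.413),
#' c = -0.021 for obesity), with province random-intercept variance 0.026.
#' Covariate marginals default to the survey sample mix (57.6% female, age
#' ~ N(46.1, 17.9^2) truncated to 18-95, education shares 10/36/36.6/17.3%).
#'
#' Intercepts are not identified by the published coefficients; by default
#' they are calibrated so the implied marginal prevalences match
#' [default_prevalence_targets()] (see [calibrate_intercepts()]). Pass
#' `calibrate = FALSE` to keep the supplied (or zero) intercepts.
#'
#' @param n_individuals cohort size.
#' @param n_provinces number of provinces.
#' @param temp_min,temp_max province temperature range, degrees C.
#' @param temp_mode `"equispaced"` or `"uniform_random"` (see
#'   [make_province_table()]).
#' @param sex_female_prob probability of female.
#' @param age_mean,age_sd,age_min,age_max truncated-normal age distribution,
#'   years.
#' @param education_probs named length-4 probability vector over
#'   `university`, `incomplete_primary`, `incomplete_secondary`,
#'   `complete_secondary`; must sum to 1.
#' @param m1_intercept,m1_temp,m1_covariate_effects fruit/vegetable adequacy
#'   equation (log-odds); `m1_temp` is the a1 path.
#' @param m2_intercepts,m2_temp,m2_covariate_effects multinomial
#'   physical-activity equation vs `low`; named `moderate`/`high` components;
#'   `m2_temp` holds the a21/a22 paths.
#' @param y_intercept,y_temp,y_m1,y_m2_moderate,y_m2_high,y_covariate_effects
#'   overweight outcome equation; `y_temp` is the direct effect c, `y_m1`,
#'   `y_m2_*` the b paths.
#' @param obesity_intercept,obesity_temp,obesity_m1,obesity_m2_moderate,obesity_m2_high,obesity_covariate_effects
#'   obesity outcome equation (same structure).
#' @param province_variance variance of the province-level random intercept
#'   entering the outcome equations.
#' @param mediator_random_intercept if `TRUE`, the province intercept also
#'   enters the mediator equations (sensitivity switch; default off, matching
#'   the outcome-only variance component of the reference model).
#' @param missing_m1_prob probability that a row's fruit/vegetable value is
#'   masked to missing (completely at random).
#' @param seed integer master seed; each sampling stage derives its own
#'   sub-stream from it.
#' @param calibrate calibrate intercepts to `targets` (default `TRUE`).
#' @param targets prevalence targets for calibration.
#'
#' @return An object of class `generator_config` (a validated named list).
#' @seealso [simulate_cohort()], [marginal_prevalence()],
#'   [calibrate_intercepts()]
#' @export
generator_config <- function(n_individuals = 16410,
                             n_provinces = 24,
                             temp_min = 4.6, temp_max = 23.0,
                             temp_mode = c("equispaced", "uniform_random"),
                             sex_female_prob = 9450 / 16410,
                             age_mean = 46.1, age_sd = 17.9,
                             age_min = 18, age_max = 95,
                             education_probs = c(
                               university = 2845 / 16410,
                               incomplete_primary = 1647 / 16410,
                               incomplete_secondary = 5906 / 16410,
                               complete_secondary = 6012 / 16410),
                             m1_intercept = 0,
                             m1_temp = 0.020,
                             m1_covariate_effects = zero_covariate_effects(),
                             m2_intercepts = c(moderate = 0, high = 0),
                             m2_temp = c(moderate = -0.015, high = -0.059),
                             m2_covariate_effects = list(
                               moderate = zero_covariate_effects(),
                               high = zero_covariate_effects()),
                             y_intercept = 0,
                             y_temp = -0.019,
                             y_m1 = 0.025,
                             y_m2_moderate = -0.168,
                             y_m2_high = -0.362,
                             y_covariate_effects = c(
                               female = -0.365, age = 0.029,
                               edu_incomplete_primary = 0.269,
                               edu_incomplete_secondary = 0.317,
                               edu_complete_secondary = 0.208),
                             obesity_intercept = 0,
                             obesity_temp = -0.021,
                             obesity_m1 = 0.018,
                             obesity_m2_moderate = -0.234,
                             obesity_m2_high = -0.413,
                             obesity_covariate_effects = c(
                               female = -0.365, age = 0.029,
                               edu_incomplete_primary = 0.269,
                               edu_incomplete_secondary = 0.317,
                               edu_complete_secondary = 0.208),
                             province_variance = 0.026,
                             mediator_random_intercept = FALSE,
                             missing_m1_prob = 455 / 16410,
                             seed = 1L,
                             calibrate = TRUE,
                             targets = default_prevalence_targets()) {
  temp_mode <- match.arg(temp_mode)
  cfg <- structure(list(
    n_individuals = n_individuals, n_provinces = n_provinces,
    temp_min = temp_min, temp_max = temp_max, temp_mode = temp_mode,
    sex_female_prob = sex_female_prob,
    age_mean = age_mean, age_sd = age_sd, age_min = age_min, age_max = age_max,
    education_probs = education_probs,
    m1_intercept = m1_intercept, m1_temp = m1_temp,
    m1_covariate_effects = fill_covariate_effects(m1_covariate_effects,
                                                  "m1_covariate_effects"),
    m2_intercepts = m2_intercepts, m2_temp = m2_temp,
    m2_covariate_effects = list(
      moderate = fill_covariate_effects(m2_covariate_effects$moderate,
                                        "m2_covariate_effects$moderate"),
      high = fill_covariate_effects(m2_covariate_effects$high,
                                    "m2_covariate_effects$high")),
    y_intercept = y_intercept, y_temp = y_temp, y_m1 = y_m1,
    y_m2_moderate = y_m2_moderate, y_m2_high = y_m2_high,
    y_covariate_effects = fill_covariate_effects(y_covariate_effects,
                                                 "y_covariate_effects"),
    obesity_intercept = obesity_intercept, obesity_temp = obesity_temp,
    obesity_m1 = obesity_m1, obesity_m2_moderate = obesity_m2_moderate,
    obesity_m2_high = obesity_m2_high,
    obesity_covariate_effects = fill_covariate_effects(
      obesity_covariate_effects, "obesity_covariate_effects"),
    province_variance = province_variance,
    mediator_random_intercept = isTRUE(mediator_random_intercept),
    missing_m1_prob = missing_m1_prob,
    seed = seed), class = "generator_config")
  validate_generator_config(cfg)
  if (isTRUE(calibrate)) cfg <- calibrate_intercepts(cfg, targets)
  cfg
}

fill_covariate_effects <- function(x, field) {
  if (is.null(x)) return(zero_covariate_effects())
  if (is.null(names(x)) && length(x) == length(.covariate_terms))
    names(x) <- .covariate_terms
  unknown <- setdiff(names(x), .covariate_terms)
  if (length(unknown))
    stop_invalid("'%s' has unknown term(s): %s", field,
                 paste(unknown, collapse = ", "))
  out <- zero_covariate_effects()
  out[names(x)] <- x
  out
}

#' @rdname generator_config
#' @param config object to validate.
#' @export
validate_generator_config <- function(config) {
  if (!inherits(config, "generator_config"))
    stop_invalid("'config' must be a generator_config object")
  assert_count(config$n_individuals, "n_individuals")
  assert_count(config$n_provinces, "n_provinces")
  assert_number(config$temp_min, "temp_min")
  assert_number(config$temp_max, "temp_max")
  if (config$temp_min > config$temp_max)
    stop_invalid("'temp_min' must be <= 'temp_max'")
  assert_prob(config$sex_female_prob, "sex_female_prob")
  assert_number(config$age_mean, "age_mean")
  if (config$age_sd <= 0) stop_invalid("'age_sd' must be positive")
  if (config$age_min >= config$age_max)
    stop_invalid("'age_min' must be < 'age_max'")
  ep <- config$education_probs
  if (length(ep) != 4L || is.null(names(ep)) ||
      !setequal(names(ep), .education_levels))
    stop_invalid("'education_probs' must be named over: %s",
                 paste(.education_levels, collapse = ", "))
  if (any(ep < 0) || abs(sum(ep) - 1) > 1e-12)
    stop_invalid("'education_probs' must be nonnegative and sum to 1 (tolerance 1e-12)")
  for (f in c("m1_intercept", "m1_temp", "y_intercept", "y_temp", "y_m1",
              "y_m2_moderate", "y_m2_high", "obesity_intercept",
              "obesity_temp", "obesity_m1", "obesity_m2_moderate",
              "obesity_m2_high"))
    assert_number(config[[f]], f)
  for (f in c("m2_intercepts", "m2_temp")) {
    v <- config[[f]]
    if (length(v) != 2L || !setequal(names(v), c("moderate", "high")) ||
        any(!is.finite(v)))
      stop_invalid("'%s' must be a finite vector named moderate, high", f)
  }
  if (!is.numeric(config$province_variance) || config$province_variance < 0)
    stop_invalid("'province_variance' must be >= 0")
  assert_prob(config$missing_m1_prob, "missing_m1_prob")
  assert_count(config$seed, "seed", min = 0L)
  invisible(config)
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Synthetic cohort generator configuration\n")
  cat(sprintf("  n = %d individuals, %d provinces (%s temps %.1f-%.1f C)\n",
              x$n_individuals, x$n_provinces, x$temp_mode,
              x$temp_min, x$temp_max))
  cat(sprintf("  paths: a1 = %.3f, a21 = %.3f, a22 = %.3f\n",
              x$m1_temp, x$m2_temp[["moderate"]], x$m2_temp[["high"]]))
  cat(sprintf("  overweight: c = %.3f, b1 = %.3f, b21 = %.3f, b22 = %.3f\n",
              x$y_temp, x$y_m1, x$y_m2_moderate, x$y_m2_high))
  cat(sprintf("  province variance = %.3f; M1 missingness = %.4f; seed = %d\n",
              x$province_variance, x$missing_m1_prob, x$seed))
  invisible(x)
}
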