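# Parallel multiple-mediator model: assembly of the three structural
# equations, product-of-coefficients effect decomposition, and the
# raw-difference contrast between indirect pathways.

.default_covariates <- c("sex", "age", "education")

build_equations <- function(outcome, covariates) {
  cov_rhs <- if (length(covariates)) paste("+", paste(covariates, collapse = " + "))
             else ""
  list(
    m1 = stats::as.formula(paste("fv_adequate ~ mean_temp_c", cov_rhs)),
    m2 = stats::as.formula(paste("pa_level ~ mean_temp_c", cov_rhs)),
    y = stats::as.formula(paste(outcome, "~ mean_temp_c + fv_adequate",
                                "+ pa_level", cov_rhs)))
}

#' Fit the parallel multiple-mediator path model
#'
#' Assembles the full path model for one outcome: (i) a logistic equation
#' for fruit/vegetable adequacy (M1) on temperature, (ii) a three-category
#' multinomial logit for physical-activity level (M2, low as reference) on
#' temperature, and (iii) a province random-intercept logistic outcome
#' equation on temperature, both mediators and the covariates. Rows with
#' missing M1 are excluded (listwise) before any fit. The structural
#' coefficients are extracted into a `path_coefficients` object: a1 (X->M1),
#' a21/a22 (X->M2 moderate/high), b1, b21, b22 (mediator->Y), the direct
#' effect c (X->Y), and the province variance sigma^2.
#'
#' @param data cohort data frame (see [simulate_cohort()] /
#'   [load_cohort_csv()]).
#' @param outcome `"overweight"` or `"obesity"`.
#' @param covariates character vector of adjustment covariates included in
#'   every equation (default sex, age, education; use `character(0)` for
#'   unadjusted mediator models).
#' @param quadrature_points adaptive quadrature nodes for the outcome
#'   equation; `0` drops the random intercept and fits plain logistic.
#' @param cluster cluster column for the outcome equation.
#' @param variance_se compute the SE of sigma^2.
#' @return A `path_coefficients` object; component `fits` holds the three
#'   `climmed_fit`s, `n_used`/`n_dropped` the listwise-deletion bookkeeping.
#' @examples
#' \donttest{
#' sim <- simulate_cohort(generator_config(n_individuals = 4000))
#' path <- assemble_path_model(sim$cohort, "overweight",
#'                             quadrature_points = 1)
#' decompose_effects(path)
#' }
#' @export
assemble_path_model <- function(data, outcome = c("overweight", "obesity"),
                                covariates = .default_covariates,
                                quadrature_points = 7L,
                                cluster = "province_id",
                                variance_se = FALSE) {
  outcome <- match.arg(outcome)
  if (!all(c("fv_adequate", "pa_level", "mean_temp_c", outcome) %in% names(data)))
    stop_invalid("data lacks required columns for the path model")
  n_total <- nrow(data)
  data <- data[!is.na(data$fv_adequate), , drop = FALSE]
  eqs <- build_equations(outcome, covariates)
  fit_m1 <- tryCatch(fit_logistic(eqs$m1, data),
                     error = function(e) stop_invalid("M1 equation: %s",
                                                      conditionMessage(e)))
  fit_m2 <- tryCatch(fit_multinomial(eqs$m2, data, reference = "low"),
                     error = function(e) stop_invalid("M2 equation: %s",
                                                      conditionMessage(e)))
  fit_y <- tryCatch({
    if (quadrature_points >= 1L)
      fit_logistic_ri(eqs$y, data, cluster, quadrature_points,
                      variance_se = variance_se)
    else fit_logistic(eqs$y, data)
  }, error = function(e) stop_invalid("outcome equation: %s",
                                      conditionMessage(e)))
  structure(list(
    a1 = unname(fit_m1$coefficients[["mean_temp_c"]]),
    a21 = unname(fit_m2$coefficients[["moderate:mean_temp_c"]]),
    a22 = unname(fit_m2$coefficients[["high:mean_temp_c"]]),
    b1 = unname(fit_y$coefficients[["fv_adequateyes"]]),
    b21 = unname(fit_y$coefficients[["pa_levelmoderate"]]),
    b22 = unname(fit_y$coefficients[["pa_levelhigh"]]),
    c = unname(fit_y$coefficients[["mean_temp_c"]]),
    sigma2 = if (quadrature_points >= 1L)
      unname(fit_y$variance_component[["sigma2"]]) else 0,
    covariate_coefficients = list(
      m1 = fit_m1$coefficients, m2 = fit_m2$coefficients,
      y = fit_y$coefficients),
    fits = list(m1 = fit_m1, m2 = fit_m2, y = fit_y),
    outcome = outcome, n_used = nrow(data), n_dropped = n_total - nrow(data)),
    class = "path_coefficients")
}

#' @export
print.path_coefficients <- function(x, digits = 3, ...) {
  cat(sprintf("Parallel mediation path coefficients (%s, n = %d, %d dropped)\n",
              x$outcome, x$n_used, x$n_dropped))
  v <- round(unlist(x[c("a1", "a21", "a22", "b1", "b21", "b22", "c", "sigma2")]),
             digits)
  print(v)
  invisible(x)
}

path_coefficients <- function(a1, a21, a22, b1, b21, b22, c, sigma2 = 0) {
  structure(list(a1 = a1, a21 = a21, a22 = a22, b1 = b1, b21 = b21, b22 = b22,
                 c = c, sigma2 = sigma2), class = "path_coefficients")
}

#' Decompose the path model into direct, indirect and total effects
#'
#' Product-of-coefficients decomposition on the log-odds scale: the direct
#' effect is c; each specific indirect effect is the exact product of its
#' two path coefficients (a1 b1 for fruit/vegetable consumption, a21 b21 and
#' a22 b22 for moderate and high physical activity); each per-path total
#' effect is c + a b; and the raw differences contrast the M1 pathway with
#' each physical-activity pathway (a1 b1 - a2i b2i). Values are stored
#' unrounded; `digits` only affects printing.
#'
#' @param path a `path_coefficients` object (fitted or constructed).
#' @param digits printing precision.
#' @return An `effect_decomposition` with components `direct`, `indirect`
#'   (named `m1`, `m21`, `m22`), `total`, and `raw_diff` (named `m1_vs_m21`,
#'   `m1_vs_m22`).
#' @examples
#' p <- list(a1 = 0.020, a21 = -0.015, a22 = -0.059,
#'           b1 = 0.025, b21 = -0.168, b22 = -0.362, c = -0.019)
#' class(p) <- "path_coefficients"
#' decompose_effects(p)
#' @export
decompose_effects <- function(path, digits = 4) {
  if (!inherits(path, "path_coefficients"))
    stop_invalid("'path' must be a path_coefficients object")
  indirect <- c(m1 = path$a1 * path$b1,
                m21 = path$a21 * path$b21,
                m22 = path$a22 * path$b22)
  structure(list(
    direct = path$c,
    indirect = indirect,
    total = path$c + indirect,
    raw_diff = c(m1_vs_m21 = unname(indirect["m1"] - indirect["m21"]),
                 m1_vs_m22 = unname(indirect["m1"] - indirect["m22"])),
    digits = digits), class = "effect_decomposition")
}

#' @export
print.effect_decomposition <- function(x, ...) {
  d <- x$digits %||% 4
  cat("Effect decomposition (log-odds scale)\n")
  cat(sprintf("  direct (c): %.*f\n", d, x$direct))
  cat("  indirect:\n")
  for (nm in names(x$indirect))
    cat(sprintf("    %-9s %.*f\n", nm, d, x$indirect[[nm]]))
  cat("  total (direct + path):\n")
  for (nm in names(x$total))
    cat(sprintf("    %-9s %.*f\n", nm, d, x$total[[nm]]))
  cat("  raw differences:\n")
  for (nm in names(x$raw_diff))
    cat(sprintf("    %-9s %.*f\n", nm, d, x$raw_diff[[nm]]))
  invisible(x)
}

#' Raw difference between two specific indirect effects
#'
#' The contrast used to compare mediator importance: the (signed) difference
#' `indirect[path_a] - indirect[path_b]` between two specific indirect
#' effects, or its magnitude in `"absolute"` mode.
#'
#' @param decomp an [decompose_effects()] result.
#' @param path_a,path_b path labels among `"m1"`, `"m21"`, `"m22"`.
#' @param mode `"signed"` (default) or `"absolute"`.
#' @return A single number.
#' @export
raw_difference <- function(decomp, path_a, path_b,
                           mode = c("signed", "absolute")) {
  if (!inherits(decomp, "effect_decomposition"))
    stop_invalid("'decomp' must be an effect_decomposition")
  mode <- match.arg(mode)
  for (p in c(path_a, path_b))
    if (!p %in% names(decomp$indirect))
      stop_invalid("unknown path label '%s'; expected one of: %s", p,
                   paste(names(decomp$indirect), collapse = ", "))
  d <- unname(decomp$indirect[[path_a]] - decomp$indirect[[path_b]])
  if (mode == "absolute") abs(d) else d
}

#' Does a bootstrap confidence interval exclude zero?
#'
#' The decision rule for a difference in magnitude between indirect effects:
#' evidence of a difference is declared iff the percentile interval excludes
#' zero. The rule is strict — an interval with an endpoint exactly at zero
#' does not exclude it.
#'
#' @param result a `bootstrap_result` (or any list with a 2-vector `ci`).
#' @return `TRUE` iff `ci[1] > 0` or `ci[2] < 0`.
#' @export
zero_excluded <- function(result) {
  ci <- result$ci
  if (is.null(ci) || length(ci) != 2L || anyNA(ci) || ci[1] > ci[2])
    stop_invalid("'result' must carry a valid 2-element ci")
  ci[1] > 0 || ci[2] < 0
}
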