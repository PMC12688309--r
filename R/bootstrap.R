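# Percentile bootstrap for the mediation estimands: each replicate resamples
# rows with replacement and refits the full three-equation pipeline.

.all_estimands <- c("direct",
                    "indirect_m1", "indirect_m21", "indirect_m22",
                    "total_m1", "total_m21", "total_m22",
                    "raw_diff_m1_m21", "raw_diff_m1_m22")

estimands_from_path <- function(path) {
  dec <- decompose_effects(path)
  c(direct = dec$direct,
    indirect_m1 = unname(dec$indirect["m1"]),
    indirect_m21 = unname(dec$indirect["m21"]),
    indirect_m22 = unname(dec$indirect["m22"]),
    total_m1 = unname(dec$total["m1"]),
    total_m21 = unname(dec$total["m21"]),
    total_m22 = unname(dec$total["m22"]),
    raw_diff_m1_m21 = unname(dec$raw_diff["m1_vs_m21"]),
    raw_diff_m1_m22 = unname(dec$raw_diff["m1_vs_m22"]))
}

#' Percentile-bootstrap inference for mediation estimands
#'
#' Draws `n_reps` bootstrap replicates, each resampling `resample_size` rows
#' with replacement from the analysis set (rows with missing fruit/vegetable
#' status are excluded first) and refitting all three structural equations;
#' from each refit the requested estimands — direct effect, specific
#' indirect effects, per-path total effects, and raw differences between
#' indirect effects — are recomputed. The 95% interval is formed from the
#' 2.5th and 97.5th empirical percentiles (order statistics, type-1
#' quantiles) of the replicate vector, and the bootstrap SE is the replicate
#' standard deviation. Replicates whose refit fails (e.g. a category absent
#' from a resample) are dropped and counted.
#'
#' For speed the replicate refits run on pre-built model matrices through
#' the package's Newton solvers (logistic IRLS; multinomial Newton-Raphson),
#' warm-started at the full-data estimates.
#' With `quadrature_points >= 1` the replicate outcome equation goes through
#' [lme4::glmer()] (much slower); with `0` it is plain logistic, a
#' negligible approximation when the province variance is small relative to
#' the coefficient sampling error.
#'
#' @param data cohort data frame.
#' @param outcome `"overweight"` or `"obesity"`.
#' @param estimands subset of `climmed_estimands()` (default: all).
#' @param n_reps number of bootstrap replicates (>= 2).
#' @param resample_size rows drawn per replicate (defaults to the analysis-set
#'   size; must not exceed it).
#' @param seed integer seed driving the whole resampling stream.
#' @param quadrature_points outcome-equation quadrature (see above).
#' @param covariates adjustment covariates for every equation.
#' @param conf_level confidence level for the percentile interval.
#' @param strict escalate a >1% replicate failure rate from warning to error.
#' @return A named list of `bootstrap_result` objects (one per estimand),
#'   with attribute `replicates`: the full replicate matrix for histogram
#'   rendering.
#' @export
bootstrap_effects <- function(data, outcome = c("overweight", "obesity"),
                              estimands = climmed_estimands(),
                              n_reps = 5000L, resample_size = NULL,
                              seed = 1L, quadrature_points = 0L,
                              covariates = .default_covariates,
                              conf_level = 0.95, strict = FALSE) {
  outcome <- match.arg(outcome)
  n_reps <- assert_count(n_reps, "n_reps", min = 2L)
  seed <- assert_count(seed, "seed", min = 0L)
  bad <- setdiff(estimands, .all_estimands)
  if (length(bad)) stop_invalid("unknown estimand(s): %s", paste(bad, collapse = ", "))
  d <- data[!is.na(data$fv_adequate), , drop = FALSE]
  n <- nrow(d)
  resample_size <- if (is.null(resample_size)) n
                   else assert_count(resample_size, "resample_size", min = 2L)
  if (resample_size > n)
    stop_invalid("resample_size (%d) exceeds the %d available rows", resample_size, n)

  # full-data point estimates through the standard path assembly
  path_full <- assemble_path_model(d, outcome, covariates,
                                   quadrature_points = quadrature_points)
  point <- estimands_from_path(path_full)

  eqs <- build_equations(outcome, covariates)
  Xc <- stats::model.matrix(stats::delete.response(stats::terms(eqs$m1)), d)
  y_m1 <- as.integer(d$fv_adequate == "yes")
  Y_pa <- stats::model.matrix(~ pa_level - 1, d)   # columns low, moderate, high
  Xy <- stats::model.matrix(stats::delete.response(stats::terms(eqs$y)), d)
  y_out <- as.integer(d[[outcome]] == "yes")

  beta_m1_full <- stats::glm.fit(Xc, y_m1, family = stats::binomial())$coefficients
  m2_full <- multinom_newton(Xc, Y_pa, matrix(0, 2L, ncol(Xc)))
  beta_y_full <- stats::glm.fit(Xy, y_out, family = stats::binomial())$coefficients
  if (anyNA(beta_m1_full) || anyNA(beta_y_full) || !m2_full$converged)
    stop_invalid("full-data equations did not fit; bootstrap aborted")
  i_temp_c <- which(colnames(Xc) == "mean_temp_c")
  i_temp_y <- which(colnames(Xy) == "mean_temp_c")
  i_b1 <- which(colnames(Xy) == "fv_adequateyes")
  i_b21 <- which(colnames(Xy) == "pa_levelmoderate")
  i_b22 <- which(colnames(Xy) == "pa_levelhigh")

  needs_m1 <- any(grepl("m1", estimands))
  fit_one <- function(idx) {
    a1 <- 0
    if (needs_m1) {
      f1 <- logistic_newton(Xc[idx, , drop = FALSE], y_m1[idx], beta_m1_full)
      if (!f1$converged || max(abs(f1$coefficients)) > 50) return(NULL)
      a1 <- f1$coefficients[i_temp_c]
    }
    f2 <- multinom_newton(Xc[idx, , drop = FALSE], Y_pa[idx, , drop = FALSE],
                          m2_full$beta, tol = 1e-9, max_iter = 50L)
    if (!f2$converged || max(abs(f2$beta)) > 50) return(NULL)
    if (quadrature_points >= 1L) {
      fy <- tryCatch(
        fit_logistic_ri(eqs$y, d[idx, , drop = FALSE], "province_id",
                        quadrature_points, variance_se = FALSE),
        error = function(e) NULL)
      if (is.null(fy)) return(NULL)
      cy <- fy$coefficients
      c_hat <- cy[["mean_temp_c"]]; b1 <- cy[["fv_adequateyes"]]
      b21 <- cy[["pa_levelmoderate"]]; b22 <- cy[["pa_levelhigh"]]
    } else {
      fy <- logistic_newton(Xy[idx, , drop = FALSE], y_out[idx], beta_y_full)
      if (!fy$converged || max(abs(fy$coefficients)) > 50) return(NULL)
      cy <- fy$coefficients
      c_hat <- cy[i_temp_y]; b1 <- cy[i_b1]; b21 <- cy[i_b21]; b22 <- cy[i_b22]
    }
    a21 <- f2$beta[1L, i_temp_c]; a22 <- f2$beta[2L, i_temp_c]
    ind <- c(a1 * b1, a21 * b21, a22 * b22)
    c(direct = unname(c_hat),
      indirect_m1 = unname(ind[1]), indirect_m21 = unname(ind[2]),
      indirect_m22 = unname(ind[3]),
      total_m1 = unname(c_hat + ind[1]), total_m21 = unname(c_hat + ind[2]),
      total_m22 = unname(c_hat + ind[3]),
      raw_diff_m1_m21 = unname(ind[1] - ind[2]),
      raw_diff_m1_m22 = unname(ind[1] - ind[3]))
  }

  reps <- matrix(NA_real_, n_reps, length(.all_estimands),
                 dimnames = list(NULL, .all_estimands))
  with_seed(seed, {
    for (r in seq_len(n_reps)) {
      idx <- sample.int(n, resample_size, replace = TRUE)
      v <- tryCatch(suppressWarnings(fit_one(idx)), error = function(e) NULL)
      # coefficients beyond +-50 log-odds signal a separated refit
      if (!is.null(v) && all(is.finite(v)) && all(abs(v) < 50)) reps[r, ] <- v
    }
  })
  n_failed <- sum(is.na(reps[, 1]))
  if (n_failed / n_reps > 0.01) {
    msg <- sprintf("%d of %d bootstrap replicates failed to refit",
                   n_failed, n_reps)
    if (strict) stop_invalid("%s", msg) else warning(msg, call. = FALSE)
  }
  alpha <- (1 - conf_level) / 2
  out <- lapply(estimands, function(e) {
    v <- reps[!is.na(reps[, e]), e]
    structure(list(
      estimand = e,
      estimate = unname(point[[e]]),
      replicates = v,
      ci = unname(stats::quantile(v, c(alpha, 1 - alpha), type = 1,
                                  names = FALSE)),
      boot_se = stats::sd(v),
      conf_level = conf_level,
      n_reps = n_reps, resample_size = resample_size, seed = seed,
      n_failed_replicates = n_failed), class = "bootstrap_result")
  })
  names(out) <- estimands
  attr(out, "replicates") <- reps[, estimands, drop = FALSE]
  attr(out, "path") <- path_full
  out
}

#' Estimand labels understood by [bootstrap_effects()]
#' @return Character vector of the nine supported estimand labels.
#' @export
climmed_estimands <- function() .all_estimands

#' @export
print.bootstrap_result <- function(x, digits = 4, ...) {
  cat(sprintf("%s: %.4f (boot SE %.4f, %g%% percentile CI %.4f; %.4f)\n",
              x$estimand, x$estimate, x$boot_se, 100 * x$conf_level,
              x$ci[1], x$ci[2]))
  cat(sprintf("  %d replicates of size %d (seed %d, %d failed)\n",
              x$n_reps, x$resample_size, x$seed, x$n_failed_replicates))
  invisible(x)
}

#' Summarise a set of bootstrap results as a data frame
#'
#' @param results the list returned by [bootstrap_effects()].
#' @return A data frame with one row per estimand: estimate, bootstrap SE,
#'   percentile CI, and whether the interval excludes zero.
#' @export
bootstrap_table <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    data.frame(estimand = r$estimand, estimate = r$estimate,
               boot_se = r$boot_se, ci_low = r$ci[1], ci_high = r$ci[2],
               zero_excluded = zero_excluded(r))
  }))
}
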