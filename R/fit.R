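# Maximum-likelihood fitting of the three structural equation families:
# binary logistic, K-category multinomial logistic, and random-intercept
# (cluster-level) logistic with adaptive Gauss-Hermite quadrature.

#' Akaike and Bayesian information criteria
#'
#' @param loglik log-likelihood at the optimum.
#' @param n_params number of free parameters (variance components included).
#' @param n_obs number of observations.
#' @return Named vector `c(aic, bic)` with `aic = 2k - 2L`,
#'   `bic = k ln(n) - 2L`.
#' @export
information_criteria <- function(loglik, n_params, n_obs) {
  assert_number(loglik, "loglik")
  assert_count(n_params, "n_params", min = 0L)
  assert_count(n_obs, "n_obs")
  c(aic = 2 * n_params - 2 * loglik,
    bic = n_params * log(n_obs) - 2 * loglik)
}

new_fit_result <- function(coefficients, vcov, loglik, n_obs, n_params,
                           converged = TRUE, n_iter = NA_integer_,
                           variance_component = NULL,
                           max_abs_gradient = NA_real_, family = "binomial") {
  stopifnot(is.numeric(coefficients), nrow(vcov) == length(coefficients))
  dimnames(vcov) <- list(names(coefficients), names(coefficients))
  ic <- information_criteria(loglik, n_params, n_obs)
  structure(list(
    coefficients = coefficients,
    standard_errors = sqrt(pmax(diag(vcov), 0)),
    vcov = vcov,
    loglik = loglik, n_obs = n_obs, n_params = n_params,
    aic = ic[["aic"]], bic = ic[["bic"]],
    variance_component = variance_component,
    converged = converged, n_iter = n_iter,
    max_abs_gradient = max_abs_gradient, family = family),
    class = "climmed_fit")
}

#' @export
print.climmed_fit <- function(x, digits = 4, ...) {
  z <- stats::qnorm(0.975)
  tab <- data.frame(estimate = x$coefficients,
                    se = x$standard_errors,
                    ci_low = x$coefficients - z * x$standard_errors,
                    ci_high = x$coefficients + z * x$standard_errors)
  cat(sprintf("%s fit: n = %d, logLik = %.2f, AIC = %.2f, BIC = %.2f\n",
              x$family, x$n_obs, x$loglik, x$aic, x$bic))
  print(round(tab, digits))
  if (!is.null(x$variance_component))
    cat(sprintf("cluster variance: %.4f (SE %.4f)\n",
                x$variance_component[["sigma2"]],
                x$variance_component[["se"]]))
  invisible(x)
}

#' Wald confidence intervals for a fitted equation
#'
#' @param object a `climmed_fit`.
#' @param parm optional coefficient names.
#' @param level confidence level.
#' @param ... unused.
#' @export
confint.climmed_fit <- function(object, parm = NULL, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  est <- object$coefficients
  se <- object$standard_errors
  out <- cbind(low = est - z * se, high = est + z * se)
  if (!is.null(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' @export
coef.climmed_fit <- function(object, ...) object$coefficients

#' @export
vcov.climmed_fit <- function(object, ...) object$vcov

#' @export
logLik.climmed_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = object$n_obs,
            class = "logLik")
}

check_binary_response <- function(y) {
  if (is.factor(y)) {
    if (nlevels(y) != 2L) stop_invalid("response must have exactly 2 levels")
    y <- as.integer(y) - 1L
  }
  if (!all(y %in% c(0, 1))) stop_invalid("response must be binary (0/1 or a 2-level factor)")
  if (length(unique(y)) < 2L)
    stop_invalid("degenerate response: all observations share one outcome, no MLE exists")
  y
}

#' Fit a binary logistic regression
#'
#' Maximum-likelihood logistic regression by iteratively reweighted least
#' squares (via [stats::glm()]) under a tight convergence tolerance, with
#' explicit failure on degenerate responses, perfect separation and
#' rank-deficient designs. Reference categories are the first factor levels
#' of the predictors (male, university education, low physical activity,
#' inadequate fruit/vegetable consumption in cohort data).
#'
#' @param formula model formula; the response may be 0/1 or a 2-level factor
#'   (second level modelled).
#' @param data data frame with no missing values in the used columns.
#' @return A `climmed_fit` with coefficients, standard errors, covariance,
#'   log-likelihood, AIC/BIC, and the maximum absolute score component at
#'   the optimum.
#' @export
fit_logistic <- function(formula, data) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  y <- check_binary_response(stats::model.response(mf))
  X <- stats::model.matrix(formula, mf)
  if (qr(X)$rank < ncol(X))
    stop_invalid("rank-deficient design: columns of the model matrix are collinear")
  fit <- withCallingHandlers(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-12, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  p <- fit$fitted.values
  if (any(p < 1e-10 | p > 1 - 1e-10)) {
    worst <- names(which.max(abs(fit$coefficients[-1])))
    stop_invalid("perfect separation detected (term '%s' diverges); no finite MLE",
                 worst %||% colnames(X)[2])
  }
  if (!fit$converged) stop_invalid("logistic fit did not converge")
  w <- p * (1 - p)
  H <- crossprod(X * sqrt(w))
  V <- solve(H)
  grad <- drop(crossprod(X, y - p))
  ll <- sum(y * log(p) + (1 - y) * log1p(-p))
  new_fit_result(fit$coefficients, V, ll, length(y), ncol(X),
                 converged = TRUE, n_iter = fit$iter,
                 max_abs_gradient = max(abs(grad)))
}

# bare-metal logistic Newton/IRLS on a prebuilt model matrix; used by the
# bootstrap replicate engine where glm.fit's per-call overhead dominates
logistic_newton <- function(X, y, beta0, tol = 1e-9, max_iter = 50L) {
  beta <- beta0
  eta <- drop(X %*% beta)
  ll <- sum(y * eta - log1p(exp(eta)))
  for (it in seq_len(max_iter)) {
    p <- stats::plogis(eta)
    g <- crossprod(X, y - p)
    H <- crossprod(X, X * (p * (1 - p)))
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) return(list(converged = FALSE))
    new_beta <- beta + drop(step)
    new_eta <- drop(X %*% new_beta)
    new_ll <- sum(y * new_eta - log1p(exp(new_eta)))
    half <- 0L
    while (!is.finite(new_ll) || new_ll < ll - 1e-12) {
      step <- step / 2; half <- half + 1L
      if (half > 30L) break
      new_beta <- beta + drop(step)
      new_eta <- drop(X %*% new_beta)
      new_ll <- sum(y * new_eta - log1p(exp(new_eta)))
    }
    done <- abs(new_ll - ll) < tol * (abs(ll) + 1) && max(abs(g)) < 1e-7
    beta <- new_beta; eta <- new_eta; ll <- new_ll
    if (done) return(list(coefficients = beta, loglik = ll, converged = TRUE,
                          n_iter = it))
  }
  list(converged = FALSE)
}

# multinomial log-likelihood, score and expected information for
# beta: (K-1) x p matrix; Y: n x K indicator; X: n x p
multinom_loglik <- function(beta, X, Y) {
  eta <- X %*% t(beta)                        # n x (K-1)
  lse <- log1p(rowSums(exp(eta)))
  sum(Y[, -1, drop = FALSE] * eta) - sum(lse)
}

multinom_newton <- function(X, Y, beta0, tol = 1e-10, max_iter = 100L) {
  p <- ncol(X); Km1 <- ncol(Y) - 1L
  beta <- beta0
  ll <- multinom_loglik(beta, X, Y)
  for (it in seq_len(max_iter)) {
    eta <- X %*% t(beta)
    expeta <- exp(eta)
    denom <- 1 + rowSums(expeta)
    P <- expeta / denom                       # n x (K-1)
    grad <- as.vector(crossprod(X, Y[, -1, drop = FALSE] - P))
    H <- matrix(0, Km1 * p, Km1 * p)
    for (k in seq_len(Km1)) for (l in k:Km1) {
      wkl <- if (k == l) P[, k] * (1 - P[, k]) else -P[, k] * P[, l]
      blk <- crossprod(X, X * wkl)
      ri <- (k - 1) * p + seq_len(p); ci <- (l - 1) * p + seq_len(p)
      H[ri, ci] <- blk
      if (l > k) H[ci, ri] <- t(blk)
    }
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step)) stop_invalid("singular information matrix in multinomial fit")
    new_beta <- beta + matrix(step, Km1, p, byrow = TRUE)
    new_ll <- multinom_loglik(new_beta, X, Y)
    # step-halving guard
    half <- 0L
    while (!is.finite(new_ll) || new_ll < ll - 1e-12) {
      step <- step / 2; half <- half + 1L
      if (half > 30L) break
      new_beta <- beta + matrix(step, Km1, p, byrow = TRUE)
      new_ll <- multinom_loglik(new_beta, X, Y)
    }
    done <- abs(new_ll - ll) < tol * (abs(ll) + 1) && max(abs(grad)) < 1e-7
    beta <- new_beta; ll <- new_ll
    if (done) return(list(beta = beta, loglik = ll, hessian = H, n_iter = it,
                          converged = TRUE, max_abs_gradient = max(abs(grad))))
  }
  list(beta = beta, loglik = ll, hessian = NULL, n_iter = max_iter,
       converged = FALSE, max_abs_gradient = NA_real_)
}

#' Fit a multinomial (baseline-category) logistic regression
#'
#' Fits the multinomial logit with a declared reference category by
#' Newton-Raphson on the categorical log-likelihood (restarting from a
#' [nnet::multinom()] solution if plain Newton stalls). With two observed
#' categories the model reduces
#' exactly to binary logistic regression. Coefficients are labelled
#' `"<category>:<term>"` for each non-reference category.
#'
#' @param formula model formula with a factor response.
#' @param data data frame with no missing values in the used columns.
#' @param reference reference category (default: first factor level, i.e.
#'   `low` for physical activity).
#' @return A `climmed_fit`; `n_params = (K-1) * p`.
#' @export
fit_multinomial <- function(formula, data, reference = NULL) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  if (!is.factor(y)) y <- factor(y)
  unobserved <- setdiff(levels(y), as.character(unique(y)))
  if (length(unobserved))
    stop_invalid("category '%s' declared but absent from data", unobserved[1])
  if (!is.null(reference)) {
    if (!(reference %in% levels(y)))
      stop_invalid("reference category '%s' absent from data", reference)
    y <- stats::relevel(y, reference)
  }
  K <- nlevels(y)
  if (K < 2L) stop_invalid("response must have at least 2 observed categories")
  X <- stats::model.matrix(formula, mf)
  if (qr(X)$rank < ncol(X))
    stop_invalid("rank-deficient design: columns of the model matrix are collinear")
  Y <- stats::model.matrix(~ y - 1)
  beta0 <- matrix(0, K - 1L, ncol(X))
  res <- multinom_newton(X, Y, beta0)
  if (!res$converged) {
    # difficult surface: restart from nnet's BFGS solution
    start <- tryCatch({
      d0 <- data.frame(.y = y, check.names = FALSE)
      fit0 <- nnet::multinom(.y ~ X - 1, data = d0, trace = FALSE,
                             maxit = 500, reltol = 1e-12)
      cf <- stats::coef(fit0)
      if (is.null(dim(cf))) matrix(cf, 1L) else unname(as.matrix(cf))
    }, error = function(e) NULL)
    if (!is.null(start) && all(is.finite(start)) &&
        identical(dim(start), dim(beta0)))
      res <- multinom_newton(X, Y, start)
  }
  if (!res$converged)
    stop_invalid("multinomial fit did not converge after %d iterations", res$n_iter)
  terms_nm <- as.vector(t(outer(levels(y)[-1], colnames(X), paste, sep = ":")))
  cf <- stats::setNames(as.vector(t(res$beta)), terms_nm)
  V <- solve(res$hessian)
  # hessian blocks are ordered category-major with terms within
  dimnames(V) <- list(terms_nm, terms_nm)
  new_fit_result(cf, V, res$loglik, nrow(X), length(cf),
                 converged = TRUE, n_iter = res$n_iter,
                 max_abs_gradient = res$max_abs_gradient,
                 family = "multinomial")
}

#' Fit a random-intercept (multilevel) logistic regression
#'
#' Cluster-level random-intercept logistic regression, the "latent
#' contextual variable" specification of the outcome equation: the marginal
#' likelihood integrates a Normal(0, sigma^2) intercept per cluster by
#' adaptive Gauss-Hermite quadrature ([lme4::glmer()]). The variance
#' component's standard error is derived from a finite-difference Hessian of
#' the deviance over (theta, beta) with the delta method
#' SE(sigma^2) = 2 sigma SE(sigma).
#'
#' @param formula fixed-effects formula.
#' @param data data frame with no missing values in the used columns.
#' @param cluster name of the cluster (province) column; at least 2 distinct
#'   clusters are required for the variance to be identified.
#' @param quadrature_points number of adaptive quadrature nodes (>= 1;
#'   1 = Laplace approximation; default 7).
#' @param variance_se compute the SE of sigma^2 (numeric Hessian; costs a
#'   few hundred extra deviance evaluations).
#' @param constrain_zero evaluate the model with sigma^2 fixed at 0
#'   (profiling only the fixed effects); used to verify the nested-model
#'   identity with plain logistic regression.
#' @return A `climmed_fit` whose `variance_component` is
#'   `c(sigma2 = ..., se = ...)`; `n_params` counts fixed effects plus the
#'   variance component.
#' @export
fit_logistic_ri <- function(formula, data, cluster,
                            quadrature_points = 7L,
                            variance_se = TRUE,
                            constrain_zero = FALSE) {
  quadrature_points <- assert_count(quadrature_points, "quadrature_points")
  if (!cluster %in% names(data))
    stop_invalid("cluster column '%s' not found", cluster)
  if (length(unique(data[[cluster]])) < 2L)
    stop_invalid("variance unidentified: need >= 2 clusters, found %d",
                 length(unique(data[[cluster]])))
  vars <- all.vars(formula)
  if (anyNA(data[c(vars, cluster)])) stop_invalid("missing values in used columns; filter first")
  check_binary_response(stats::model.frame(
    stats::update(formula, . ~ 1), data)[[1]])
  fml <- stats::as.formula(paste(paste(deparse(formula), collapse = " "),
                                 "+ (1 |", cluster, ")"))
  converged <- TRUE
  g <- withCallingHandlers(
    lme4::glmer(fml, data = data, family = stats::binomial(),
                nAGQ = quadrature_points,
                control = lme4::glmerControl(optimizer = "bobyqa",
                                             calc.derivs = FALSE)),
    warning = function(w) {
      converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  devfun <- lme4::glmer(fml, data = data, family = stats::binomial(),
                        nAGQ = quadrature_points, devFunOnly = TRUE)
  beta <- lme4::fixef(g)
  theta <- lme4::getME(g, "theta")
  if (constrain_zero) {
    # at theta = 0 the marginal likelihood is the plain-logistic likelihood,
    # whose optimum IRLS locates to machine precision
    plain <- fit_logistic(formula, data)
    beta <- plain$coefficients
    ll <- -devfun(c(0, unname(beta))) / 2
    # information for beta at theta = 0 equals the plain-logistic information
    X <- stats::model.matrix(formula, data)
    p <- stats::plogis(drop(X %*% beta))
    V <- solve(crossprod(X * sqrt(p * (1 - p))))
    return(new_fit_result(stats::setNames(beta, colnames(X)), V, ll,
                          nrow(data), ncol(X) , converged = TRUE,
                          variance_component = c(sigma2 = 0, se = NA_real_),
                          family = "binomial (sigma^2 = 0)"))
  }
  sigma2 <- unname(theta)^2
  ll <- as.numeric(stats::logLik(g))
  V_beta <- as.matrix(stats::vcov(g))
  se_sig2 <- NA_real_
  if (variance_se && sigma2 > 1e-10) {
    se_sig2 <- tryCatch({
      nll <- function(par) devfun(par) / 2
      H <- pracma::hessian(nll, c(theta, beta))
      Vfull <- solve(H)
      v_theta <- Vfull[1, 1]
      if (v_theta > 0) 2 * abs(unname(theta)) * sqrt(v_theta) else NA_real_
    }, error = function(e) NA_real_)
  }
  n_par <- length(beta) + 1L
  new_fit_result(beta, V_beta, ll, nrow(data), n_par,
                 converged = converged,
                 variance_component = c(sigma2 = sigma2, se = se_sig2),
                 family = sprintf("binomial, random intercept (AGQ %d)",
                                  quadrature_points))
}

#' Sequential model ladder for a clustered binary outcome
#'
#' Reproduces the stepwise build-up of the outcome model: (1) temperature
#' only, (2) + sex, age, education, (3) + physical activity and
#' fruit/vegetable adequacy — each as a province random-intercept logistic
#' fit — with an AIC/BIC comparison table. Rows with missing fruit/vegetable
#' status are excluded from Model 3 only (the first models use all rows).
#'
#' @param data cohort data frame.
#' @param outcome `"overweight"` or `"obesity"`.
#' @param quadrature_points adaptive quadrature nodes.
#' @param variance_se compute SEs for the variance components.
#' @return A list with `fits` (named list of `climmed_fit`) and `table`
#'   (model, n, n_params, loglik, aic, bic).
#' @export
fit_model_ladder <- function(data, outcome = c("overweight", "obesity"),
                             quadrature_points = 7L, variance_se = FALSE) {
  outcome <- match.arg(outcome)
  f1 <- stats::as.formula(paste(outcome, "~ mean_temp_c"))
  f2 <- stats::update(f1, . ~ . + sex + age + education)
  f3 <- stats::update(f2, . ~ . + pa_level + fv_adequate)
  d3 <- data[!is.na(data$fv_adequate), , drop = FALSE]
  fits <- list(
    model1 = fit_logistic_ri(f1, data, "province_id", quadrature_points,
                             variance_se = variance_se),
    model2 = fit_logistic_ri(f2, data, "province_id", quadrature_points,
                             variance_se = variance_se),
    model3 = fit_logistic_ri(f3, d3, "province_id", quadrature_points,
                             variance_se = variance_se))
  tab <- do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    data.frame(model = nm, n = f$n_obs, n_params = f$n_params,
               loglik = f$loglik, aic = f$aic, bic = f$bic)
  }))
  list(fits = fits, table = tab)
}
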