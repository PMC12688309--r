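# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_invalid("'%s' must be a single probability in [0, 1]", name)
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x))
    stop_invalid("'%s' must be a single integer >= %d", name, min)
  invisible(as.integer(x))
}

assert_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid("'%s' must be a single finite number", name)
  invisible(x)
}

# Fixed sub-stream ordering: each sampling step of the generator draws under
# its own seed derived from (seed, stage index), so adding a later stage never
# perturbs draws of earlier stages.
.sim_stages <- c(
  province_temp = 1L, province_assign = 2L, random_intercept = 3L,
  sex = 4L, age = 5L, education = 6L, m1 = 7L, m2 = 8L,
  overweight = 9L, obesity = 10L, missing_m1 = 11L,
  obesity_random_intercept = 12L
)

stage_seed <- function(seed, stage) {
  idx <- .sim_stages[[stage]]
  as.integer((as.double(seed) * 31L + idx * 1000003) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Gauss-Hermite nodes/weights rewritten for N(mu, sigma2) expectations:
# E[f(b)] ~ sum_k w_k f(x_k)
gauss_hermite_normal <- function(k, mu = 0, sigma2 = 0) {
  if (sigma2 <= 0) return(list(nodes = mu, weights = 1))
  gh <- pracma::gaussHermite(k)
  list(nodes = mu + sqrt(2 * sigma2) * gh$x,
       weights = gh$w / sqrt(pi))
}
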