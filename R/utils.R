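#' @importFrom rlang %||% abort warn
#' @importFrom stats density rnorm rpois runif rbinom sd median setNames
#' @importFrom utils head tail
NULL

# Otsu's threshold on a numeric vector: maximizes between-class variance of
# the histogram. Used for focus-gate calibration and for image masks.
otsu_threshold <- function(x, n_breaks = 256L) {
  x <- x[is.finite(x)]
  if (length(x) < 2L || diff(range(x)) == 0) {
    return(if (length(x)) x[1] else NA_real_)
  }
  h <- graphics::hist(x, breaks = seq(min(x), max(x), length.out = n_breaks + 1L),
                      plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  omega <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[length(mu)]
  denom <- omega * (1 - omega)
  sigma_b2 <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, 0)
  k <- which.max(head(sigma_b2, -1L))
  (mids[k] + mids[k + 1L]) / 2
}

# Location of the density minimum of `x` inside a window. Falls back to
# `default` when too few points are available for a stable estimate.
density_valley <- function(x, window, default, min_n = 50L) {
  x <- x[is.finite(x)]
  if (length(x) < min_n) return(default)
  d <- stats::density(x, n = 512L, from = window[1], to = window[2])
  d$x[which.max(-d$y)]
}

# run `expr` under a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  withr::with_seed(seed, expr)
}

# correlated bivariate standard normal draws
rbinorm <- function(n, rho) {
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  cbind(z1, z2)
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be > 0.", name))
  }
  invisible(x)
}
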