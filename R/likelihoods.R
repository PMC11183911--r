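#' Numerically stable inverse-logit
#'
#' Maps a real linear predictor to a probability. Stable for large `|x|`:
#' never overflows, returns 0/1 only in the exact limits.
#'
#' @param x Numeric vector of finite values on the logit scale.
#' @return Probabilities `1 / (1 + exp(-x))`.
#' @examples
#' inv_logit(0)     # 0.5
#' inv_logit(-800)  # 0, no overflow
#' @export
inv_logit <- function(x) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stop("inv_logit: 'x' must be finite numeric", call. = FALSE)
  # plogis is the stable logistic CDF; identical to 1/(1+exp(-x))
  stats::plogis(x)
}

#' Gamma log-density in mean/shape form
#'
#' Density of a Gamma distribution parameterized by its mean `mu` and shape
#' `shape`, i.e. shape `k` and rate `k / mu`, so that `E[Y] = mu` and
#' `Var[Y] = mu^2 / k`.
#'
#' @param y Positive numeric vector of observed values.
#' @param mu Positive mean parameter (vector or scalar).
#' @param shape Positive shape parameter `k`.
#' @param log Logical; return log-density (default `TRUE`).
#' @return (Log-)density values.
#' @export
dgamma_mean_shape <- function(y, mu, shape, log = TRUE) {
  if (any(y <= 0) || anyNA(y)) stop("dgamma_mean_shape: 'y' must be > 0", call. = FALSE)
  if (any(mu <= 0) || anyNA(mu)) stop("dgamma_mean_shape: 'mu' must be > 0", call. = FALSE)
  if (any(shape <= 0) || anyNA(shape)) stop("dgamma_mean_shape: 'shape' must be > 0", call. = FALSE)
  stats::dgamma(y, shape = shape, rate = shape / mu, log = log)
}

#' Convert a mean/shape Gamma parameterization to shape/rate
#'
#' @param mu Positive mean.
#' @param shape Positive shape `k`.
#' @return Named numeric vector `c(shape, rate)` with `rate = shape / mu`.
#' @export
mean_shape_to_shape_rate <- function(mu, shape) {
  if (any(mu <= 0) || any(shape <= 0) || anyNA(mu) || anyNA(shape))
    stop("mean_shape_to_shape_rate: 'mu' and 'shape' must be > 0", call. = FALSE)
  c(shape = shape, rate = shape / mu)
}

#' Hurdle-Gamma log-density
#'
#' Two-part density for a semicontinuous non-negative outcome: a point mass
#' `1 - pi_open` at exactly zero (wound closed) and, conditional on being
#' positive, a Gamma in mean/shape form scaled by `pi_open`.
#'
#' @param y Non-negative numeric vector (0 = closed wound).
#' @param pi_open Probability in `[0, 1]` that the outcome is positive.
#' @param mu Positive conditional Gamma mean.
#' @param shape Positive Gamma shape.
#' @param log Logical; return log-density (default `TRUE`).
#' @return (Log-)density values; `-Inf` where a branch has probability zero.
#' @export
dhurdle_gamma <- function(y, pi_open, mu, shape, log = TRUE) {
  if (any(y < 0) || anyNA(y)) stop("dhurdle_gamma: 'y' must be >= 0", call. = FALSE)
  if (any(pi_open < 0 | pi_open > 1) || anyNA(pi_open))
    stop("dhurdle_gamma: 'pi_open' must be in [0, 1]", call. = FALSE)
  if (any(mu <= 0) || any(shape <= 0))
    stop("dhurdle_gamma: 'mu' and 'shape' must be > 0", call. = FALSE)
  n <- max(length(y), length(pi_open), length(mu), length(shape))
  y <- rep_len(y, n); pi_open <- rep_len(pi_open, n)
  mu <- rep_len(mu, n); shape <- rep_len(shape, n)
  out <- numeric(n)
  zero <- y == 0
  out[zero] <- log1p(-pi_open[zero])            # log(1 - pi_open), stable near 1
  if (any(!zero)) {
    out[!zero] <- log(pi_open[!zero]) +
      dgamma_mean_shape(y[!zero], mu[!zero], shape[!zero], log = TRUE)
  }
  if (log) out else exp(out)
}

#' Negative-binomial log-mass in mean/dispersion form
#'
#' Mass of a negative binomial with mean `mu` and dispersion `phi`, so that
#' `Var[Y] = mu + mu^2 / phi`; the Poisson limit is `phi -> Inf`. Equivalent
#' to the Gamma-Poisson mixture with Gamma shape `phi` and mean `mu`.
#'
#' @param y Non-negative integer vector of counts.
#' @param mu Positive mean.
#' @param phi Positive dispersion.
#' @param log Logical; return log-mass (default `TRUE`).
#' @return (Log-)mass values.
#' @export
dnbinom_mean_disp <- function(y, mu, phi, log = TRUE) {
  if (anyNA(y) || any(y < 0) || any(y != floor(y)))
    stop("dnbinom_mean_disp: 'y' must be non-negative integers", call. = FALSE)
  if (any(mu <= 0) || any(phi <= 0))
    stop("dnbinom_mean_disp: 'mu' and 'phi' must be > 0", call. = FALSE)
  stats::dnbinom(y, size = phi, mu = mu, log = log)
}
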