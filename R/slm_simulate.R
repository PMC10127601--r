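#' Simulate stochastic logistic model (SLM) abundance trajectories
#'
#' Integrates the stochastic logistic SDE
#' \deqn{dx/dt = x/\tau (1 - x/K) + \sqrt{\sigma/\tau}\, x\, \eta(t)}
#' by Euler--Maruyama under the Ito interpretation and returns the abundance
#' sampled at the requested days. `K` is the carrying capacity (relative
#' abundance units), `sigma` the dimensionless environmental-noise amplitude
#' and `tau` the growth timescale in days. For `sigma > 0` the long-run
#' distribution of abundance is the stationary gamma of
#' [stationary_gamma_pdf()]; `sigma = 0` gives the deterministic logistic.
#'
#' The integration substep is `min(0.02 * tau, 0.02)` days, and trajectories
#' are floored at a small positive value (`1e-12`) so that the discretised
#' multiplicative noise cannot drive the abundance to or below zero.
#'
#' @param days numeric vector of strictly increasing observation days; the
#'   trajectory starts at `days[1]` with value `x0`.
#' @param x0 positive initial abundance(s); one value per path.
#' @param K carrying capacity, `K > 0` (recycled across paths).
#' @param sigma noise amplitude, `0 <= sigma < 2` (recycled).
#' @param tau growth timescale in days, `tau > 0` (recycled).
#' @param n_paths number of independent paths; defaults to `length(x0)`.
#'
#' @return If one path, a numeric vector along `days`; otherwise a matrix
#'   with one row per path and one column per day.
#' @examples
#' set.seed(1)
#' x <- simulate_slm_trajectory(0:100, x0 = 0.1, K = 0.1, sigma = 0.4)
#' @export
simulate_slm_trajectory <- function(days, x0, K, sigma, tau = 1,
                                    n_paths = length(x0)) {
  days <- as.numeric(days)
  if (length(days) < 1L || anyNA(days) || any(diff(days) <= 0)) {
    stop("`days` must be strictly increasing and free of NAs")
  }
  if (any(K <= 0)) stop("invalid SLM parameter: K must be > 0")
  if (any(sigma < 0 | sigma >= 2)) {
    stop("invalid SLM parameter: sigma must lie in [0, 2)")
  }
  if (any(tau <= 0)) stop("invalid SLM parameter: tau must be > 0")
  if (any(x0 <= 0)) stop("`x0` must be positive")
  x0 <- rep_len(as.numeric(x0), n_paths)
  out <- slm_paths_cpp(days, x0, as.numeric(K), as.numeric(sigma),
                       as.numeric(tau), 0.02, 1e-12)
  dimnames(out) <- list(NULL, NULL)
  if (n_paths == 1L) drop(out) else out
}

#' Stationary gamma distribution of the SLM
#'
#' For `0 < sigma < 2` the stationary abundance distribution of the
#' stochastic logistic model is a gamma with shape `2/sigma - 1` and scale
#' `K * sigma / 2`, so that the mean is `K (1 - sigma/2)` and the variance
#' `K^2 (sigma/2) (1 - sigma/2)`.
#'
#' @param x positive quantiles.
#' @param K carrying capacity (> 0).
#' @param sigma noise amplitude in (0, 2).
#' @return `stationary_gamma_pdf` returns the density; `stationary_gamma_cdf`
#'   the distribution function; `rstationary_gamma` draws `n` samples.
#' @export
stationary_gamma_pdf <- function(x, K, sigma) {
  p <- .check_gamma_params(K, sigma)
  dgamma(x, shape = p$shape, scale = p$scale)
}

#' @rdname stationary_gamma_pdf
#' @export
stationary_gamma_cdf <- function(x, K, sigma) {
  p <- .check_gamma_params(K, sigma)
  pgamma(x, shape = p$shape, scale = p$scale)
}

#' @rdname stationary_gamma_pdf
#' @param n number of draws.
#' @export
rstationary_gamma <- function(n, K, sigma) {
  p <- .check_gamma_params(K, sigma)
  rgamma(n, shape = p$shape, scale = p$scale)
}

.check_gamma_params <- function(K, sigma) {
  if (any(K <= 0)) stop("K must be > 0")
  if (any(sigma <= 0 | sigma >= 2)) {
    stop("sigma must lie in (0, 2) for a proper stationary distribution")
  }
  list(shape = 2 / sigma - 1, scale = K * sigma / 2)
}
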