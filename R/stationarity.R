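#' Augmented Dickey-Fuller stationarity test
#'
#' Classifies a time series (here, typically a species' F_ST' trajectory)
#' as stationary or nonstationary with an augmented Dickey-Fuller (ADF)
#' unit-root test. The null hypothesis is that the series contains a unit
#' root (is nonstationary); rejecting it at `alpha` is evidence that the
#' mean and variance of the series are time invariant.
#'
#' The test regression includes a constant but no deterministic trend
#' (F_ST' has no natural trend under the stationary hypothesis):
#' \deqn{\Delta y_t = c + \gamma y_{t-1} + \sum_{i=1}^{p}\phi_i
#'   \Delta y_{t-i} + e_t,}
#' with the lag order p chosen automatically by AIC over `0..max_lag`
#' (Schwert's rule `12 (n/100)^{1/4}` caps the search, all candidate fits
#' sharing one estimation sample). The t-statistic on \eqn{\gamma} is
#' compared with MacKinnon's (1994) approximate asymptotic distribution for
#' the constant-only regression to obtain the p-value.
#'
#' Non-finite observations are dropped. A constant (zero-variance) series
#' is classified stationary by convention, flagged as degenerate.
#'
#' @param series numeric vector; at least 10 finite observations.
#' @param max_lag maximum lag order searched; default Schwert's rule.
#' @param alpha significance level for the stationary call (default 0.05).
#' @return An object of class `adf_test`: list with `statistic`, `p_value`,
#'   `stationary` (p < alpha), `lag` (selected order), `n` (observations
#'   used) and `degenerate`.
#' @examples
#' set.seed(1)
#' adf_stationarity(rnorm(200))          # i.i.d. noise: stationary
#' adf_stationarity(cumsum(rnorm(200)))  # random walk: usually not
#' @export
adf_stationarity <- function(series, max_lag = NULL, alpha = 0.05) {
  y <- as.numeric(series)
  y <- y[is.finite(y)]
  n <- length(y)
  if (n < 10L) stop("need at least 10 finite observations for the ADF test")
  if (sd(y) == 0) {
    return(structure(list(statistic = NA_real_, p_value = 0,
                          stationary = TRUE, lag = 0L, n = n,
                          degenerate = TRUE),
                     class = "adf_test"))
  }
  if (is.null(max_lag)) {
    max_lag <- min(ceiling(12 * (n / 100)^0.25), n %/% 2 - 2)
  }
  max_lag <- max(0L, as.integer(max_lag))
  dy <- diff(y)

  # lag search on the common sample trimmed at max_lag, AIC = n log(RSS/n) + 2k
  resp <- dy[(max_lag + 1):(n - 1)]
  nr <- length(resp)
  lev <- y[(max_lag + 1):(n - 1)]
  lagmat <- if (max_lag > 0) {
    vapply(seq_len(max_lag), function(k) dy[(max_lag + 1 - k):(n - 1 - k)],
           numeric(nr))
  } else NULL
  aics <- vapply(0:max_lag, function(k) {
    X <- cbind(1, lev, if (k > 0) lagmat[, seq_len(k), drop = FALSE])
    rss <- .ols_rss(X, resp)
    nr * log(rss / nr) + 2 * (k + 2)
  }, numeric(1))
  best <- which.min(aics) - 1L

  # refit the selected order on the full usable sample
  resp <- dy[(best + 1):(n - 1)]
  lev <- y[(best + 1):(n - 1)]
  X <- cbind(1, lev)
  if (best > 0) {
    X <- cbind(X, vapply(seq_len(best),
                         function(k) dy[(best + 1 - k):(n - 1 - k)],
                         numeric(length(resp))))
  }
  fit <- .ols_t(X, resp)
  stat <- fit$coef[2] / fit$se[2]
  p <- .mackinnon_p(stat)
  structure(list(statistic = unname(stat), p_value = p,
                 stationary = p < alpha, lag = best,
                 n = length(resp), degenerate = FALSE),
            class = "adf_test")
}

#' @export
print.adf_test <- function(x, ...) {
  cat(sprintf("ADF test: statistic = %.4f, p = %.4g, lag = %d, n = %d -> %s%s\n",
              x$statistic, x$p_value, x$lag, x$n,
              if (x$stationary) "stationary" else "nonstationary",
              if (x$degenerate) " (degenerate: constant series)" else ""))
  invisible(x)
}

.ols_rss <- function(X, y) {
  fit <- .lm.fit(X, y)
  sum(fit$residuals^2)
}

.ols_t <- function(X, y) {
  qx <- qr(X)
  b <- qr.coef(qx, y)
  res <- y - X %*% b
  s2 <- sum(res^2) / (nrow(X) - ncol(X))
  se <- sqrt(diag(chol2inv(qr.R(qx))) * s2)
  list(coef = b, se = se)
}

# MacKinnon (1994) approximate asymptotic p-value for the Dickey-Fuller
# t-statistic, constant-only regression, one integrated series:
# p = Phi(polynomial(stat)), with separate polynomials for small and large
# statistics and hard 0/1 tails outside the tabulated range.
.mackinnon_p <- function(stat) {
  if (!is.finite(stat)) return(NA_real_)
  if (stat > 2.74) return(1)
  if (stat < -18.83) return(0)
  co <- if (stat <= -1.61) {
    c(2.1659, 1.4412, 0.038269)
  } else {
    c(1.7339, 0.93202, -0.12745, -0.010368)
  }
  pnorm(sum(co * stat^(seq_along(co) - 1)))
}
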