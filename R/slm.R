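#' Fit SLM parameters by moment matching
#'
#' Under the stochastic logistic model the stationary abundance
#' distribution is a gamma with mean `K (1 - sigma/2)` and variance
#' `K^2 (sigma/2)(1 - sigma/2)`, so the carrying capacity and noise
#' amplitude are functions of the observed mean and variance rather than
#' free parameters. With training mean m and variance v:
#' \deqn{\beta = v / (m^2 + v), \quad \sigma = 2\beta, \quad
#'   K = m / (1 - \beta) = m + v/m.}
#'
#' The growth timescale tau is not identifiable from stationary moments
#' and is carried through as supplied (default 1 day).
#'
#' @param x positive abundance observations (the training window).
#' @param tau growth timescale in days attached to the fit (default 1).
#' @return object of class `slm_fit`: list with `K`, `sigma`, `tau`,
#'   `mean`, `var`, `n`, `degenerate` (TRUE when the variance is 0, in
#'   which case `sigma = 0` and no stationary distribution exists).
#' @examples
#' fit_slm_moments(rstationary_gamma(1000, K = 0.1, sigma = 0.4))
#' @export
fit_slm_moments <- function(x, tau = 1) {
  x <- as.numeric(x)
  if (anyNA(x) || any(x <= 0)) stop("abundances must be positive and non-NA")
  if (length(x) < 5L) stop("need at least 5 training observations")
  m <- mean(x)
  v <- var(x)
  if (v == 0) {
    return(structure(list(K = m, sigma = 0, tau = tau, mean = m, var = 0,
                          n = length(x), degenerate = TRUE),
                     class = "slm_fit"))
  }
  beta <- v / (m^2 + v)
  structure(list(K = m / (1 - beta), sigma = 2 * beta, tau = tau,
                 mean = m, var = v, n = length(x), degenerate = FALSE),
            class = "slm_fit")
}

#' @export
print.slm_fit <- function(x, ...) {
  cat(sprintf("SLM fit: K = %.4g, sigma = %.4g, tau = %g (n = %d%s)\n",
              x$K, x$sigma, x$tau, x$n,
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' Parametric-bootstrap goodness-of-fit test of the SLM
#'
#' Tests whether an abundance trajectory is consistent with a stochastic
#' logistic model whose parameters were estimated from the first third of
#' the time series. Qualitatively, a population obeying the SLM should
#' have a held-out mean and variance matching the training window, and a
#' tendency to revert towards its carrying capacity.
#'
#' The training window is the first `ceiling(T/3)` time points by index;
#' the rest is held out. Three statistics are computed on the held-out
#' window: (s1) the absolute difference between held-out and training
#' means; (s2) the absolute log-ratio of held-out to training variance;
#' (s3) a reversion statistic, the regression slope of the abundance
#' increments on `(x - K)` across successive held-out transitions
#' (negative under mean reversion). Their null distribution is built by
#' simulating `n_boot` surrogate trajectories from the fitted SLM over
#' the full observed day grid, initialized at the first observation; each
#' surrogate is split into the same training/held-out windows, its SLM
#' parameters are refitted on its own training window, and the three
#' statistics are recomputed relative to those refitted quantities. This
#' propagates the estimation noise of the training-window moments into
#' the null, which is essential for calibration: conditioning on the
#' observed training fit as if it were exact makes the observed
#' mean/variance shifts overdispersed relative to the surrogates and
#' inflates the rejection rate severalfold. Each statistic gets a
#' two-sided rank p-value with the `(r + 1)/(n_boot + 1)` convention, and
#' the combined p-value is the smallest of the three,
#' Bonferroni-multiplied by 3 and capped at 1. The trajectory passes at
#' `p >= alpha`.
#'
#' @param x positive abundance observations.
#' @param days observation days (strictly increasing), same length.
#' @param fit an [fit_slm_moments()] result; computed from the training
#'   window if `NULL`.
#' @param n_boot number of surrogate trajectories (default 1000).
#' @param tau growth timescale used for the surrogates (default: the
#'   fit's tau). The statistics are chosen to be robust to tau.
#' @param train_frac fraction of time points used for training (default
#'   1/3, taken as the first `ceiling(T/3)` samples).
#' @param alpha pass threshold (default 0.05).
#' @return object of class `slm_gof`: list with `p_value`, `pass`,
#'   `statistics` (observed s1..s3), `p_each`, `fit`, `n_boot`,
#'   `status` (`"ok"` or `"degenerate"`; degenerate fits skip the test).
#' @export
slm_goodness_of_fit <- function(x, days = seq_along(x), fit = NULL,
                                n_boot = 1000, tau = NULL,
                                train_frac = 1 / 3, alpha = 0.05) {
  x <- as.numeric(x)
  days <- as.numeric(days)
  if (length(x) != length(days)) stop("`x` and `days` must have equal length")
  nt <- length(x)
  n_train <- ceiling(nt * train_frac)
  held <- (n_train + 1):nt
  if (length(held) < 10L) stop("need at least 10 held-out time points")
  if (is.null(fit)) fit <- fit_slm_moments(x[seq_len(n_train)])
  if (fit$degenerate) {
    return(structure(list(p_value = NA_real_, pass = NA, statistics = NULL,
                          p_each = NULL, fit = fit, n_boot = n_boot,
                          status = "degenerate"),
                     class = "slm_gof"))
  }
  if (is.null(tau)) tau <- fit$tau
  xh <- x[held]
  obs <- .gof_stats(xh, fit$mean, fit$var, fit$K)

  sur <- simulate_slm_trajectory(days, x0 = rep(x[1], n_boot), K = fit$K,
                                 sigma = fit$sigma, tau = tau,
                                 n_paths = n_boot)
  null_s <- .gof_stats_matrix_refit(sur, n_train)

  p_each <- vapply(1:3, function(k)
    .rank_p_two_sided(obs[k], null_s[, k]), numeric(1))
  p <- min(1, 3 * min(p_each))
  structure(list(p_value = p, pass = p >= alpha,
                 statistics = setNames(obs, c("mean_shift", "log_var_ratio",
                                              "reversion_slope")),
                 p_each = p_each, fit = fit, n_boot = n_boot, status = "ok"),
            class = "slm_gof")
}

#' @export
print.slm_gof <- function(x, ...) {
  if (x$status != "ok") {
    cat("SLM goodness-of-fit: skipped (", x$status, ")\n", sep = "")
  } else {
    cat(sprintf("SLM goodness-of-fit: p = %.4g -> %s\n",
                x$p_value, if (x$pass) "pass" else "fail"))
  }
  invisible(x)
}

#' Fit and test the SLM across many populations
#'
#' Applies [fit_slm_moments()] and [slm_goodness_of_fit()] to each
#' population (strain- or species-level abundance series) and tabulates
#' the results; per-population failures are recorded, not fatal.
#'
#' @param populations named list of positive abundance vectors, all on the
#'   same day grid.
#' @param days shared observation days.
#' @param level character vector (recycled) labelling each population,
#'   e.g. `"strain"` or `"species"`.
#' @param n_boot,tau,train_frac,alpha passed to [slm_goodness_of_fit()].
#' @return data.frame with one row per population: `population`, `level`,
#'   `K`, `sigma`, `tau`, `p_value`, `pass`, `status`.
#' @export
run_slm_battery <- function(populations, days, level = "strain",
                            n_boot = 1000, tau = 1, train_frac = 1 / 3,
                            alpha = 0.05) {
  if (length(populations) == 0L) {
    return(data.frame(population = character(), level = character(),
                      K = numeric(), sigma = numeric(), tau = numeric(),
                      p_value = numeric(), pass = logical(),
                      status = character(), stringsAsFactors = FALSE))
  }
  nm <- names(populations)
  if (is.null(nm)) nm <- paste0("pop_", seq_along(populations))
  level <- rep_len(level, length(populations))
  rows <- lapply(seq_along(populations), function(i) {
    res <- tryCatch({
      g <- slm_goodness_of_fit(populations[[i]], days, n_boot = n_boot,
                               tau = tau, train_frac = train_frac,
                               alpha = alpha)
      data.frame(population = nm[i], level = level[i], K = g$fit$K,
                 sigma = g$fit$sigma, tau = g$fit$tau, p_value = g$p_value,
                 pass = g$pass, status = g$status, stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(population = nm[i], level = level[i], K = NA_real_,
                 sigma = NA_real_, tau = tau, p_value = NA_real_, pass = NA,
                 status = paste0("error: ", conditionMessage(e)),
                 stringsAsFactors = FALSE)
    })
    res
  })
  do.call(rbind, rows)
}

# ---- internal ---------------------------------------------------------------

.gof_stats <- function(xh, m_train, v_train, K) {
  s1 <- abs(mean(xh) - m_train)
  s2 <- abs(log(var(xh) / v_train))
  dx <- diff(xh)
  z <- xh[-length(xh)] - K
  s3 <- if (sd(z) == 0) 0 else sum((z - mean(z)) * dx) / sum((z - mean(z))^2)
  c(s1, s2, s3)
}

# per-surrogate statistics with the SLM refitted on the surrogate's own
# training window, so training-moment estimation noise enters the null
.gof_stats_matrix_refit <- function(sur, n_train) {
  tr <- sur[, seq_len(n_train), drop = FALSE]
  hd <- sur[, -seq_len(n_train), drop = FALSE]
  n_tr <- ncol(tr)
  n_hd <- ncol(hd)
  m_b <- rowMeans(tr)
  v_b <- rowSums((tr - m_b)^2) / (n_tr - 1)
  beta <- v_b / (m_b^2 + v_b)
  K_b <- m_b / (1 - beta)
  mu <- rowMeans(hd)
  v <- rowSums((hd - mu)^2) / (n_hd - 1)
  s1 <- abs(mu - m_b)
  s2 <- abs(log(v / v_b))
  dx <- hd[, -1, drop = FALSE] - hd[, -n_hd, drop = FALSE]
  z <- hd[, -n_hd, drop = FALSE] - K_b
  zc <- z - rowMeans(z)
  s3 <- rowSums(zc * dx) / rowSums(zc^2)
  s3[!is.finite(s3)] <- 0
  s2[!is.finite(s2)] <- 0
  cbind(s1, s2, s3)
}

.rank_p_two_sided <- function(obs, null) {
  B <- length(null)
  p_hi <- (sum(null >= obs) + 1) / (B + 1)
  p_lo <- (sum(null <= obs) + 1) / (B + 1)
  min(1, 2 * min(p_hi, p_lo))
}
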