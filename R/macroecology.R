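#' Fit Taylor's law across populations
#'
#' Taylor's law is the power-law scaling of the temporal variance of a
#' population's abundance with its temporal mean,
#' \deqn{\sigma^2_x \propto \langle x \rangle^{\alpha},}
#' fitted here by ordinary least squares of `log10(variance)` on
#' `log10(mean)` across populations. `alpha = 1` arises when the only
#' source of variability is compositional sampling noise; `alpha = 2` when
#' all populations share the same per-capita fluctuation amplitude
#' (e.g. stochastic-logistic populations with a common sigma).
#'
#' @param abundance matrix (populations x samples) of relative abundances,
#'   or a list of per-population abundance vectors.
#' @return object of class `taylor_fit`: list with `alpha` (slope),
#'   `intercept`, `n_populations`, and `points` (data.frame of per-
#'   population mean and variance). Populations with nonpositive mean or
#'   zero variance are excluded with a warning; fewer than 3 usable
#'   populations is an error.
#' @examples
#' m <- 10^seq(-4, -1, length.out = 20)
#' fit_taylors_law(cbind(m, m * 2))$alpha  # not meaningful: 2 samples
#' @export
fit_taylors_law <- function(abundance) {
  if (is.list(abundance) && !is.data.frame(abundance)) {
    m <- vapply(abundance, mean, numeric(1))
    v <- vapply(abundance, var, numeric(1))
    nm <- names(abundance)
  } else {
    abundance <- as.matrix(abundance)
    m <- rowMeans(abundance)
    v <- apply(abundance, 1, var)
    nm <- rownames(abundance)
  }
  if (is.null(nm)) nm <- paste0("pop_", seq_along(m))
  usable <- is.finite(m) & is.finite(v) & m > 0 & v > 0
  if (any(!usable)) {
    warning(sum(!usable), " population(s) with nonpositive mean or zero ",
            "variance excluded from the Taylor fit")
  }
  if (sum(usable) < 3L) stop("need at least 3 usable populations")
  fit <- lm(log10(v[usable]) ~ log10(m[usable]))
  structure(list(alpha = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 n_populations = sum(usable),
                 points = data.frame(population = nm, mean = m, variance = v,
                                     used = usable,
                                     stringsAsFactors = FALSE)),
            class = "taylor_fit")
}

#' @export
print.taylor_fit <- function(x, ...) {
  cat(sprintf("Taylor's law: alpha = %.3f (intercept %.3f, %d populations)\n",
              x$alpha, x$intercept, x$n_populations))
  invisible(x)
}

#' Rescale an abundance-fluctuation distribution (AFD)
#'
#' Log-transforms a population's abundance observations and standardizes
#' them to zero mean and unit variance, putting every population's AFD on
#' a common scale so distributions can be compared and averaged across
#' populations. Zero or negative abundances (a strain undetected at a
#' time point) are dropped before taking logs.
#'
#' @param x abundance observations; at least 10 positive values required.
#' @return numeric vector of standardized log abundances (mean 0, sd 1).
#' @export
rescale_afd <- function(x) {
  x <- as.numeric(x)
  x <- x[is.finite(x) & x > 0]
  if (length(x) < 10L) stop("need at least 10 positive observations")
  lx <- log(x)
  s <- sd(lx)
  if (s == 0) stop("zero variance in log abundance; AFD undefined")
  (lx - mean(lx)) / s
}

#' Fit the gamma abundance-fluctuation distribution to pooled rescaled AFDs
#'
#' Bins each population's rescaled (standardized log) abundance
#' distribution on a common grid of `n_bins` even bins, averages the bin
#' densities across populations, and fits the single-parameter
#' standardized log-gamma density to the bin means by least squares. If X
#' is gamma with shape a, the standardized `log X` has density
#' \deqn{g(z \mid a) = \sqrt{\psi_1(a)} \exp\{a u - e^{u}\} / \Gamma(a),
#'   \quad u = \psi(a) + z \sqrt{\psi_1(a)},}
#' independent of the gamma scale; location and scale are fixed by the
#' zero-mean unit-variance constraint, leaving only the shape free. Under
#' the SLM the shape is `2/sigma - 1`, so a collapse of all rescaled AFDs
#' onto one such curve is the gamma-AFD macroecological law.
#'
#' @param rescaled list of numeric vectors, one per population, each
#'   already standardized by [rescale_afd()] (a single vector is accepted).
#' @param n_bins number of bins (default 20).
#' @param range standardized range covered by the grid (default
#'   `c(-4, 4)`); observations outside it are ignored for binning but
#'   still counted in the densities' normalization.
#' @return object of class `gamma_afd_fit`: list with `bin_mid`,
#'   `bin_means`, `densities` (populations x bins), `shape` (fitted gamma
#'   shape), `sigma` (the SLM noise amplitude implied by the shape,
#'   `2/(shape + 1)`), and `converged`.
#' @export
fit_gamma_afd <- function(rescaled, n_bins = 20, range = c(-4, 4)) {
  if (is.numeric(rescaled)) rescaled <- list(rescaled)
  if (length(rescaled) < 1L) stop("need at least one population")
  breaks <- seq(range[1], range[2], length.out = n_bins + 1)
  width <- diff(breaks)[1]
  dens <- t(vapply(rescaled, function(z) {
    n <- length(z)
    idx <- findInterval(z, breaks, rightmost.closed = TRUE)
    counts <- tabulate(idx[idx >= 1 & idx <= n_bins], nbins = n_bins)
    counts / (n * width)
  }, numeric(n_bins)))
  bin_means <- colMeans(dens)
  mid <- (breaks[-1] + breaks[-length(breaks)]) / 2

  # the data are bin-averaged densities, so the model must be averaged
  # over each bin too (evaluating it at midpoints biases the shape for
  # curved densities at this bin width); Simpson's rule per bin
  simpson <- function(a) {
    g <- function(z) standardized_loggamma_pdf(z, a)
    (g(breaks[-length(breaks)]) + 4 * g(mid) + g(breaks[-1])) / 6
  }
  obj <- function(loga) {
    sum((simpson(exp(loga)) - bin_means)^2)
  }
  opt <- optimize(obj, interval = log(c(0.03, 100)))
  shape <- exp(opt$minimum)
  structure(list(bin_mid = mid, bin_means = bin_means, densities = dens,
                 shape = shape, sigma = 2 / (shape + 1),
                 objective = opt$objective,
                 converged = is.finite(opt$objective)),
            class = "gamma_afd_fit")
}

#' @export
print.gamma_afd_fit <- function(x, ...) {
  cat(sprintf("Gamma AFD fit: shape = %.3f (implied SLM sigma = %.3f) over %d populations\n",
              x$shape, x$sigma, nrow(x$densities)))
  invisible(x)
}

#' Density of the standardized log of a gamma variate
#'
#' Exact density of `z = (log X - E log X) / sd(log X)` for
#' `X ~ Gamma(shape)`; scale-free, so it depends on the shape alone.
#'
#' @param z quantiles on the standardized log scale.
#' @param shape gamma shape parameter (> 0).
#' @return density values.
#' @export
standardized_loggamma_pdf <- function(z, shape) {
  if (shape <= 0) stop("shape must be positive")
  s <- sqrt(trigamma(shape))
  u <- digamma(shape) + z * s
  exp(shape * u - exp(u) - lgamma(shape)) * s
}
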