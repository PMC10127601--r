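#' Within-sample nucleotide diversity (pi)
#'
#' Genome-wide average heterozygosity of reads within a sample,
#' \deqn{\pi = \frac{1}{|G|}\sum_i \left[\frac{r_i}{d_i}\frac{a_i}{d_i-1} +
#'   \frac{a_i}{d_i}\frac{r_i}{d_i-1}\right],}
#' where \eqn{r_i}, \eqn{a_i}, \eqn{d_i} are the reference count, alternate
#' count and depth at site i. Sites with depth below `min_depth` (default
#' 5x) are excluded because allele frequencies cannot be estimated reliably
#' there, and `|G|` counts only the sites that pass the filter, so the
#' estimate is robust to coverage differences between samples. The number
#' of sites used is attached as attribute `n_sites`.
#'
#' @param tab an [snv_table()].
#' @param sample sample index (or name); if `NULL`, pi is computed for
#'   every sample and returned as a vector.
#' @param min_depth minimum per-site depth (default 5).
#' @return numeric value(s) of pi; `NA` when no site passes the filter.
#' @export
compute_pi <- function(tab, sample = NULL, min_depth = 5) {
  stopifnot(inherits(tab, "snv_table"))
  if (is.null(sample)) {
    out <- vapply(seq_along(tab$samples), function(j)
      compute_pi(tab, j, min_depth), numeric(1))
    names(out) <- tab$samples
    return(out)
  }
  j <- .resolve_sample(tab, sample)
  d <- tab$depth[, j]
  keep <- d >= min_depth
  if (!any(keep)) {
    out <- NA_real_
    attr(out, "n_sites") <- 0L
    return(out)
  }
  r <- tab$ref[keep, j]
  a <- tab$alt[keep, j]
  d <- d[keep]
  out <- mean(2 * r * a / (d * (d - 1)))
  attr(out, "n_sites") <- sum(keep)
  out
}

#' Between-sample nucleotide diversity (pi_BT)
#'
#' Cross-sample heterozygosity between two samples,
#' \deqn{\pi_{BT} = \frac{1}{|G|}\sum_i \left[\frac{r_{1i}}{d_{1i}}
#'   \frac{a_{2i}}{d_{2i}} + \frac{a_{1i}}{d_{1i}}\frac{r_{2i}}{d_{2i}}\right],}
#' averaged over the sites with depth of at least `min_depth` in both
#' samples. Symmetric in its two sample arguments.
#'
#' @inheritParams compute_pi
#' @param sample_i,sample_j sample indices or names.
#' @return pi_BT, with attribute `n_sites`; `NA` if no site passes in both.
#' @export
compute_pi_between <- function(tab, sample_i, sample_j, min_depth = 5) {
  stopifnot(inherits(tab, "snv_table"))
  i <- .resolve_sample(tab, sample_i)
  j <- .resolve_sample(tab, sample_j)
  keep <- tab$depth[, i] >= min_depth & tab$depth[, j] >= min_depth
  if (!any(keep)) {
    out <- NA_real_
    attr(out, "n_sites") <- 0L
    return(out)
  }
  f1 <- tab$alt[keep, i] / tab$depth[keep, i]
  f2 <- tab$alt[keep, j] / tab$depth[keep, j]
  out <- mean((1 - f1) * f2 + f1 * (1 - f2))
  attr(out, "n_sites") <- sum(keep)
  out
}

#' Fixation index between two samples of one species
#'
#' \deqn{F_{ST}(i,j) = \frac{\pi_{BT} - (\pi_i + \pi_j)/2}{\pi_{BT}}.}
#' Values can be slightly negative for near-identical samples because the
#' within-sample estimator carries a finite-depth correction; negative
#' values are reported as-is (clipping would bias downstream stationarity
#' testing).
#'
#' @inheritParams compute_pi_between
#' @return F_ST; `NA` (undefined) when pi_BT is 0, i.e. no between-sample
#'   diversity at the usable sites.
#' @export
compute_fst <- function(tab, sample_i, sample_j, min_depth = 5) {
  pbt <- compute_pi_between(tab, sample_i, sample_j, min_depth)
  if (is.na(pbt) || pbt == 0) return(NA_real_)
  pi_i <- compute_pi(tab, sample_i, min_depth)
  pi_j <- compute_pi(tab, sample_j, min_depth)
  as.numeric((pbt - (pi_i + pi_j) / 2) / pbt)
}

#' F_ST time series relative to the initial time point
#'
#' Computes, for every sample, pi, pi_BT against the baseline sample,
#' F_ST and the normalized F_ST' (= F_ST divided by the species' mean
#' between-host F_ST). The baseline defaults to the first sample; in the
#' pipeline it is the first day the species passes inclusion criteria.
#'
#' @inheritParams compute_pi
#' @param normalizer positive scalar: the species' cross-host mean F_ST
#'   (see [crosshost_mean_fst()]). `F_ST' ~ 1` means an intra-host change of
#'   between-host magnitude.
#' @param baseline index of the baseline sample (default 1).
#' @return data.frame with one row per sample: `sample`, `day`, `pi`,
#'   `pi_bt`, `fst`, `fst_prime`, `n_sites`. The denominator convention
#'   (sites passing the depth filter, not genome length) is recorded in
#'   attribute `denominator`.
#' @export
fst_series <- function(tab, normalizer = 1, min_depth = 5, baseline = 1L) {
  stopifnot(inherits(tab, "snv_table"))
  if (normalizer <= 0) stop("`normalizer` must be positive")
  ns <- length(tab$samples)
  pi_all <- compute_pi(tab, NULL, min_depth)
  pbt <- rep(NA_real_, ns)
  nsites <- integer(ns)
  for (j in seq_len(ns)) {
    v <- compute_pi_between(tab, baseline, j, min_depth)
    pbt[j] <- v
    nsites[j] <- attr(v, "n_sites")
  }
  fst <- ifelse(!is.na(pbt) & pbt > 0,
                (pbt - (pi_all[baseline] + pi_all) / 2) / pbt, NA_real_)
  out <- data.frame(sample = tab$samples, day = tab$days, pi = unname(pi_all),
                    pi_bt = pbt, fst = as.numeric(fst),
                    fst_prime = as.numeric(fst) / normalizer,
                    n_sites = nsites, stringsAsFactors = FALSE)
  attr(out, "denominator") <- "sites_passing_depth_filter"
  attr(out, "normalizer") <- normalizer
  out
}

#' Normalize an F_ST series by the cross-host mean F_ST
#'
#' Elementwise division of intra-host F_ST values by a species' mean
#' between-host F_ST, yielding F_ST' on a scale where 1 means an
#' intra-host change as large as typical differences between hosts.
#'
#' @param fst numeric vector of F_ST values.
#' @param crosshost_mean_fst positive scalar normalizer.
#' @return numeric vector of F_ST' values.
#' @export
normalize_fst <- function(fst, crosshost_mean_fst) {
  if (!is.numeric(crosshost_mean_fst) || length(crosshost_mean_fst) != 1L ||
      is.na(crosshost_mean_fst) || crosshost_mean_fst <= 0) {
    stop("`crosshost_mean_fst` must be a positive scalar")
  }
  fst / crosshost_mean_fst
}

#' Mean pairwise F_ST of a species across hosts
#'
#' Given a panel in which each sample column is a different host carrying
#' the species, computes the pairwise F_ST for every unordered pair of
#' hosts and returns the mean. This is the normalizer that puts intra-host
#' F_ST trajectories on the between-host scale.
#'
#' @param panel an [snv_table()] whose samples are cross-host samples.
#' @param min_depth per-site depth filter (default 5).
#' @return scalar mean F_ST across host pairs.
#' @export
crosshost_mean_fst <- function(panel, min_depth = 5) {
  stopifnot(inherits(panel, "snv_table"))
  ns <- length(panel$samples)
  if (ns < 2L) stop("need at least 2 hosts to compute a cross-host mean F_ST")
  pairs <- utils::combn(ns, 2)
  vals <- apply(pairs, 2, function(p)
    compute_fst(panel, p[1], p[2], min_depth))
  mean(vals, na.rm = TRUE)
}

.resolve_sample <- function(tab, sample) {
  if (is.character(sample)) {
    j <- match(sample, tab$samples)
    if (is.na(j)) stop("unknown sample: ", sample)
    return(j)
  }
  j <- as.integer(sample)
  if (j < 1L || j > length(tab$samples)) stop("sample index out of range")
  j
}
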