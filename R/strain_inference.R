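#' Cluster SNV frequency trajectories into putative strain backgrounds
#'
#' Conspecific strains that colonized a host independently differ at
#' thousands of fixed sites, so the alternate-allele frequencies at those
#' sites all track the frequency of the strain carrying them (up to which
#' allele is labelled "alternate"). This function finds large clusters of
#' SNVs whose trajectories are tightly correlated after polarity
#' adjustment; each such cluster is evidence of one strain segregating
#' against the rest of the population.
#'
#' Algorithm: candidate sites are those whose frequency enters
#' `freq_range` at some time point (near-fixed sites carry no trajectory
#' signal). Correlations between sites are *noise-corrected*: binomial
#' read sampling adds a variance of `p(1-p)/d` to each observed
#' frequency, which attenuates the plain Pearson correlation between
#' same-strain sites far below 1 at realistic depths (to roughly 0.3-0.8
#' at 20-50x, depending on how much the strain actually moves). The
#' sampling variance is estimated per site as the time average of
#' `f(1-f)/(d-1)` (unbiased for `p(1-p)/d`) and subtracted from the
#' trajectory variance before forming the correlation, so sites tracking
#' the same strain correlate near +/-1 regardless of depth while sites on
#' different strains keep their true-signal correlation. Sites whose
#' variance does not exceed their sampling-noise floor are dropped as
#' uninformative. Sites are clustered by average-linkage agglomeration on
#' the distance `1 - |cor|` cut at `1 - cor_threshold` (the absolute
#' value makes the clustering invariant to ref/alt label flips); for very
#' large candidate sets a subsample of `max_cluster_sites` is clustered
#' and all remaining candidates are assigned to the centroid they
#' correlate with best, provided `|cor| >= cor_threshold`. Clusters whose
#' centroids are mutually correlated above the threshold are merged, and
#' only clusters with strictly more than `min_cluster_size` members are
#' reported. No reported cluster means a single strain is present.
#'
#' @param tab an [snv_table()].
#' @param min_cluster_size minimum SNVs per reported cluster (strictly
#'   greater than; default 1000, the scale of fixed differences between
#'   true strains, which excludes within-host lineage diversification).
#' @param cor_threshold noise-corrected trajectory correlation required
#'   for co-membership (default 0.8).
#' @param freq_range frequency window defining intermediate-frequency
#'   candidate sites (default `c(0.1, 0.9)`).
#' @param min_depth per-site depth filter for frequency estimates.
#' @param max_cluster_sites cap on sites entering the pairwise-correlation
#'   stage (default 3000); further candidates are centroid-assigned.
#' @return list of clusters, each a list with `sites` (site ids), `flip`
#'   (logical polarity per member: `TRUE` means the trajectory is mirrored
#'   as `1 - f` to align with the centroid), and `centroid` (per-timepoint
#'   median of polarity-aligned raw frequencies). Ordered by decreasing
#'   size. Empty list when no large cluster exists.
#' @export
cluster_snv_trajectories <- function(tab, min_cluster_size = 1000,
                                     cor_threshold = 0.8,
                                     freq_range = c(0.1, 0.9),
                                     min_depth = 5,
                                     max_cluster_sites = 3000) {
  stopifnot(inherits(tab, "snv_table"))
  if (length(tab$samples) < 2L) stop("need at least 2 time points")
  f <- allele_frequencies(tab, min_depth)
  inter <- f >= freq_range[1] & f <= freq_range[2]
  nobs <- rowSums(is.finite(f))
  cand <- which(rowSums(inter, na.rm = TRUE) > 0 & nobs >= 3)
  if (length(cand) == 0L) return(list())
  fc <- f[cand, , drop = FALSE]
  d <- tab$depth[cand, , drop = FALSE]

  # per-site sampling-noise floor and excess (signal) variance
  noise <- fc * (1 - fc) / pmax(d - 1, 1)
  noise[!is.finite(fc)] <- NA_real_
  noise_i <- rowMeans(noise, na.rm = TRUE)
  var_i <- apply(fc, 1, function(z) var(z, na.rm = TRUE))
  sig_i <- var_i - noise_i
  keep <- is.finite(sig_i) & sig_i > 0
  cand <- cand[keep]
  fc <- fc[keep, , drop = FALSE]
  sig_i <- sig_i[keep]
  if (length(cand) == 0L) return(list())

  # pairwise stage on (at most) max_cluster_sites sites, deterministic pick
  sub <- if (length(cand) > max_cluster_sites) {
    round(seq(1, length(cand), length.out = max_cluster_sites))
  } else seq_along(cand)
  cv <- .pairwise_cov(fc[sub, , drop = FALSE])
  cm <- cv / sqrt(outer(sig_i[sub], sig_i[sub]))
  cm <- pmin(pmax(cm, -1), 1)
  cm[!is.finite(cm)] <- 0
  diag(cm) <- 1
  # the tree is cut at a stricter level than the site-assignment
  # threshold: average linkage averages away per-pair estimation noise,
  # and any over-fragmentation is repaired by the centroid-merge step
  # below, whereas a spurious union of two strains cannot be undone
  dist <- stats::as.dist(1 - abs(cm))
  grp <- stats::cutree(stats::hclust(dist, method = "average"),
                       h = (1 - cor_threshold) / 2)

  # provisional centroids from groups already plausible as strain clusters
  min_seed <- max(3L, ceiling(min_cluster_size *
                                length(sub) / length(cand) / 2))
  sizes <- table(grp)
  ids <- names(sizes)[sizes >= min_seed]
  if (length(ids) == 0L) return(list())
  cents <- lapply(ids, function(g)
    .aligned_centroid(fc[sub[grp == as.integer(g)], , drop = FALSE]))

  # merge clusters that are fragments of one strain: centroids are medians
  # of many sites and so nearly noise-free, which lets the merge test be
  # much stricter than the site-level threshold (fragments of one strain
  # correlate near 1; distinct strains essentially never reach 0.95+)
  cents <- .merge_centroids(cents, 1 - (1 - cor_threshold) / 4)

  # assign every candidate site to its best centroid; centroids are
  # medians of many member sites, so only the site's own noise needs
  # correcting in the site-centroid correlation
  cc <- vapply(cents, function(ct)
    abs(.corrected_cor_with(fc, sig_i, ct)), numeric(nrow(fc)))
  cc <- matrix(cc, nrow = nrow(fc))
  bestk <- max.col(cc, ties.method = "first")
  bestv <- cc[cbind(seq_len(nrow(cc)), bestk)]
  assigned <- which(is.finite(bestv) & bestv >= cor_threshold)

  clusters <- list()
  for (k in seq_along(cents)) {
    members <- assigned[bestk[assigned] == k]
    if (length(members) <= min_cluster_size) next
    raw <- fc[members, , drop = FALSE]
    rho <- .signed_cor_with(raw, cents[[k]])
    flip <- !is.na(rho) & rho < 0
    aligned <- raw
    aligned[flip, ] <- 1 - aligned[flip, ]
    clusters[[length(clusters) + 1L]] <- list(
      sites = tab$site_id[cand[members]],
      flip = unname(flip),
      centroid = apply(aligned, 2, median, na.rm = TRUE)
    )
  }
  ord <- order(vapply(clusters, function(cl) length(cl$sites), integer(1)),
               decreasing = TRUE)
  .orient_clusters(clusters[ord])
}

# Global polarization: each centroid may track a strain's frequency or its
# mirror (1 - f); with three or more strains the orientation matters
# because the residual strain is 1 - sum(centroids). Pick, over all 2^m
# orientation combinations, the one whose centroid sum violates the
# compositional constraint (sum <= 1) least; ties keep the current
# orientation. Member polarity flags are flipped along with the centroid.
.orient_clusters <- function(clusters) {
  m <- length(clusters)
  if (m < 2L) return(clusters)
  cents <- do.call(rbind, lapply(clusters, `[[`, "centroid"))
  combos <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), m)))
  obj <- apply(combos, 1, function(fl) {
    cc <- cents
    cc[fl, ] <- 1 - cc[fl, ]
    mean(pmax(colSums(cc, na.rm = TRUE) - 1, 0))
  })
  best <- combos[which.min(obj), ]
  for (k in which(best)) {
    clusters[[k]]$centroid <- 1 - clusters[[k]]$centroid
    clusters[[k]]$flip <- !clusters[[k]]$flip
  }
  clusters
}

#' Polarize one SNV trajectory against a cluster centroid
#'
#' A site's alternate allele may ride on either of the two haplotype
#' backgrounds that a cluster separates, so roughly half of the member
#' trajectories are mirror images (`1 - f`) of the strain frequency. This
#' returns the trajectory or its mirror, whichever correlates positively
#' with the centroid.
#'
#' @param site_freqs numeric vector of per-timepoint frequencies (may
#'   contain NA); at least 2 finite values.
#' @param centroid numeric vector, same length.
#' @return list with `flip` (logical; `NA` when the trajectory has zero
#'   variance, in which case polarity is undefined and the site should be
#'   excluded from centroid refinement) and `aligned` (the polarity-adjusted
#'   trajectory).
#' @export
polarize_trajectory <- function(site_freqs, centroid) {
  if (length(site_freqs) != length(centroid)) {
    stop("`site_freqs` and `centroid` must have equal length")
  }
  ok <- is.finite(site_freqs) & is.finite(centroid)
  if (sum(ok) < 2L) stop("need at least 2 finite frequency observations")
  if (sd(site_freqs[ok]) == 0 || sd(centroid[ok]) == 0) {
    return(list(flip = NA, aligned = site_freqs))
  }
  rho <- cor(site_freqs[ok], centroid[ok])
  flip <- !is.na(rho) && rho < 0
  list(flip = flip, aligned = if (flip) 1 - site_freqs else site_freqs)
}

#' Strain frequency trajectories from SNV clusters
#'
#' Each cluster centroid (per-timepoint median of polarity-aligned member
#' frequencies) is taken as the frequency trajectory of one strain; the
#' residual background strain gets frequency `1 - sum(centroids)`, clipped
#' to `[0, 1]`. Frequencies are renormalized to sum to exactly 1 at every
#' time point, so a species with m reported clusters carries m + 1 strains
#' (no cluster = a single strain at frequency 1).
#'
#' @param clusters output of [cluster_snv_trajectories()].
#' @param tab the [snv_table()] the clusters came from (supplies the time
#'   grid, and the frequency field for the no-cluster case).
#' @return numeric matrix, strains x time points, rows named
#'   `strain_1 ... strain_m, background`, columns carrying the days; every
#'   column sums to 1. Attribute `days` holds the day grid. A warning is
#'   issued if raw centroid sums exceed 1.1 anywhere (possible
#'   mis-clustering).
#' @export
strain_frequencies <- function(clusters, tab) {
  stopifnot(inherits(tab, "snv_table"))
  nt <- length(tab$days)
  if (length(clusters) == 0L) {
    out <- matrix(1, 1, nt, dimnames = list("strain_1", NULL))
    attr(out, "days") <- tab$days
    return(out)
  }
  cents <- do.call(rbind, lapply(clusters, `[[`, "centroid"))
  cents[!is.finite(cents)] <- NA_real_
  # carry last finite value across gaps so sums stay defined
  for (i in seq_len(nrow(cents))) {
    cents[i, ] <- .fill_na(cents[i, ])
  }
  tot <- colSums(cents)
  if (any(tot > 1.1)) {
    warning("cluster centroid frequencies sum to > 1.1 at some time points; ",
            "possible mis-clustering")
  }
  resid <- pmin(pmax(1 - tot, 0), 1)
  freqs <- rbind(cents, resid)
  freqs <- sweep(freqs, 2, colSums(freqs), "/")
  rownames(freqs) <- c(paste0("strain_", seq_len(nrow(cents))), "background")
  attr(freqs, "days") <- tab$days
  freqs
}

#' Strain abundance trajectories
#'
#' Converts within-species strain frequencies into community-level
#' relative abundances by multiplying, at each time point, the strain
#' frequency by the relative abundance of its species. Strain abundances
#' therefore sum to the species abundance at every time point.
#'
#' @param strain_freqs matrix from [strain_frequencies()] (strains x time).
#' @param species_abundance numeric vector of species relative abundance,
#'   one entry per time point.
#' @param days optional day grid of `species_abundance`; if both this and
#'   the `days` attribute of `strain_freqs` are present they must agree.
#' @return matrix of the same shape as `strain_freqs`.
#' @export
strain_abundances <- function(strain_freqs, species_abundance, days = NULL) {
  if (ncol(strain_freqs) != length(species_abundance)) {
    stop("day grids of strain frequencies and species abundance differ")
  }
  fd <- attr(strain_freqs, "days")
  if (!is.null(days) && !is.null(fd) && !isTRUE(all.equal(days, fd))) {
    stop("day grids of strain frequencies and species abundance differ")
  }
  out <- sweep(strain_freqs, 2, species_abundance, "*")
  attr(out, "days") <- fd
  out
}

#' Infer the strain content of one species
#'
#' Convenience wrapper: clusters SNV trajectories, derives strain
#' frequency and abundance trajectories, and reports the strain count
#' (number of clusters + 1 residual background strain).
#'
#' @inheritParams cluster_snv_trajectories
#' @param species_abundance optional per-timepoint species relative
#'   abundance for strain abundances.
#' @param ... further arguments passed to [cluster_snv_trajectories()].
#' @param detection_threshold frequency above which a strain is reported
#'   detected at a time point (reporting only; default 0.05).
#' @return object of class `strain_set`: list with `n_strains`, `clusters`,
#'   `frequencies`, `abundances` (NULL if no species abundance given),
#'   `detected` (logical matrix) and `days`.
#' @export
infer_strains <- function(tab, species_abundance = NULL,
                          detection_threshold = 0.05, ...) {
  clusters <- cluster_snv_trajectories(tab, ...)
  freqs <- strain_frequencies(clusters, tab)
  ab <- if (!is.null(species_abundance)) {
    strain_abundances(freqs, species_abundance)
  }
  structure(list(n_strains = nrow(freqs), clusters = clusters,
                 frequencies = freqs, abundances = ab,
                 detected = freqs >= detection_threshold,
                 days = tab$days),
            class = "strain_set")
}

#' @export
print.strain_set <- function(x, ...) {
  cat(sprintf("<strain_set> %d strain(s) from %d SNV cluster(s) over %d time points\n",
              x$n_strains, length(x$clusters), length(x$days)))
  invisible(x)
}

# ---- internal helpers -------------------------------------------------------

.fill_na <- function(x) {
  if (!anyNA(x)) return(x)
  idx <- which(is.finite(x))
  if (length(idx) == 0L) return(rep(0, length(x)))
  stats::approx(idx, x[idx], xout = seq_along(x), rule = 2)$y
}

.aligned_centroid <- function(raw) {
  ref <- which.max(apply(raw, 1, function(z) var(z, na.rm = TRUE)))
  rho <- .signed_cor_with(raw, raw[ref, ])
  flip <- !is.na(rho) & rho < 0
  a_raw <- raw
  a_raw[flip, ] <- 1 - a_raw[flip, ]
  apply(a_raw, 2, median, na.rm = TRUE)
}

.signed_cor_with <- function(m, v) {
  suppressWarnings(apply(m, 1, function(z) {
    ok <- is.finite(z) & is.finite(v)
    if (sum(ok) < 3 || sd(z[ok]) == 0 || sd(v[ok]) == 0) return(NA_real_)
    cor(z[ok], v[ok])
  }))
}

# pairwise-complete covariance of the rows of m, via dense matrix products
# (stats::cov's pairwise path is a slow loop)
.pairwise_cov <- function(m) {
  W <- is.finite(m)
  Z <- m
  Z[!W] <- 0
  Wn <- W * 1
  nij <- Wn %*% t(Wn)
  Sxy <- Z %*% t(Z)
  Sx <- Z %*% t(Wn)
  (Sxy - Sx * t(Sx) / nij) / (nij - 1)
}

# correlation of each row of m with centroid v, with the row's sampling
# noise removed from its variance (the centroid is treated as noise-free)
.corrected_cor_with <- function(m, sig, v) {
  suppressWarnings(vapply(seq_len(nrow(m)), function(i) {
    z <- m[i, ]
    ok <- is.finite(z) & is.finite(v)
    if (sum(ok) < 3 || sig[i] <= 0) return(NA_real_)
    sv <- sd(v[ok])
    if (sv == 0) return(NA_real_)
    r <- stats::cov(z[ok], v[ok]) / (sqrt(sig[i]) * sv)
    max(min(r, 1), -1)
  }, numeric(1)))
}

.merge_centroids <- function(cents, cor_threshold) {
  repeat {
    n <- length(cents)
    if (n < 2L) return(cents)
    merged <- FALSE
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        rho <- suppressWarnings(cor(cents[[i]], cents[[j]],
                                    use = "pairwise.complete.obs"))
        if (is.finite(rho) && abs(rho) >= cor_threshold) {
          # keep the i-th orientation; drop j (its members will be
          # reassigned to the surviving centroid)
          cents <- cents[-j]
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) return(cents)
  }
}
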