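#' SNV time-series table for one species in one host
#'
#' Container for per-site, per-sample allele counts from a metagenomic
#' time series: reference count, alternate count and depth (ref + alt) at
#' every genomic site, for every sampled day. This mirrors the per-site
#' output of read-mapping SNV callers (MIDAS-style), with 1-based positions
#' encoded in `site_id`.
#'
#' @param ref integer matrix (sites x samples) of reference-allele counts.
#' @param alt integer matrix of alternate-allele counts, same shape.
#' @param days numeric vector of collection days, one per sample column.
#' @param site_id optional character vector of site identifiers
#'   (e.g. `"contig|position"`); defaults to `site_1 ... site_n`.
#' @param samples optional character vector of sample names; defaults to
#'   `t<day>`.
#' @return An object of class `snv_table`: a list with elements `ref`,
#'   `alt`, `depth`, `days`, `site_id`, `samples`.
#' @examples
#' tab <- snv_table(ref = matrix(5, 1, 2), alt = matrix(5, 1, 2),
#'                  days = c(0, 1))
#' compute_pi(tab)
#' @export
snv_table <- function(ref, alt, days, site_id = NULL, samples = NULL) {
  ref <- as.matrix(ref)
  alt <- as.matrix(alt)
  if (!all(dim(ref) == dim(alt))) stop("`ref` and `alt` must have equal dimensions")
  if (length(days) != ncol(ref)) stop("`days` must have one entry per sample column")
  if (anyNA(ref) || anyNA(alt)) stop("allele counts must not be NA (use 0 depth for missing)")
  if (any(ref < 0) || any(alt < 0)) stop("allele counts must be non-negative")
  if (any(diff(order(days)) < 0)) days <- days # order checked by callers needing it
  if (is.null(site_id)) site_id <- paste0("site_", seq_len(nrow(ref)))
  if (is.null(samples)) samples <- make.unique(paste0("t", days), sep = "_")
  structure(
    list(ref = unname(ref), alt = unname(alt), depth = unname(ref + alt),
         days = as.numeric(days), site_id = as.character(site_id),
         samples = as.character(samples)),
    class = "snv_table"
  )
}

#' @export
print.snv_table <- function(x, ...) {
  cat(sprintf("<snv_table> %d sites x %d samples, days %s..%s\n",
              nrow(x$ref), ncol(x$ref),
              format(min(x$days)), format(max(x$days))))
  invisible(x)
}

#' @export
dim.snv_table <- function(x) dim(x$ref)

#' Alternate-allele frequency matrix
#'
#' Per-site, per-sample alternate-allele frequency `alt / depth`, with `NA`
#' where the depth is below `min_depth` (reliable frequency estimates
#' require adequate coverage).
#'
#' @param tab an [snv_table()].
#' @param min_depth minimum depth for a site/sample to yield a frequency.
#' @return numeric matrix (sites x samples) of frequencies in `[0, 1]`.
#' @export
allele_frequencies <- function(tab, min_depth = 5) {
  stopifnot(inherits(tab, "snv_table"))
  f <- tab$alt / tab$depth
  f[tab$depth < min_depth] <- NA_real_
  f
}

#' Read / write SNV time-series tables
#'
#' Plain-TSV serialisation with one row per site and a triplet of columns
#' `<sample>_ref`, `<sample>_alt`, `<sample>_depth` per sample, plus a
#' leading `site_id` column. Collection days are supplied through a sample
#' metadata table (`sample`, `day`), as in the pipeline input layout.
#'
#' @param path file path of the TSV.
#' @param days numeric vector of days, one per sample (in column order); if
#'   `NULL`, days are parsed from sample names of the form `t<day>`.
#' @return `read_snv_table` returns an [snv_table()]; `write_snv_table`
#'   invisibly returns `path`.
#' @export
read_snv_table <- function(path, days = NULL) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  cols <- names(dt)
  refc <- grep("_ref$", cols, value = TRUE)
  samples <- sub("_ref$", "", refc)
  ref <- as.matrix(dt[, paste0(samples, "_ref"), with = FALSE])
  alt <- as.matrix(dt[, paste0(samples, "_alt"), with = FALSE])
  if (is.null(days)) {
    days <- suppressWarnings(as.numeric(sub("^t", "", samples)))
    # samples that are not time points (e.g. cross-host panels) get an
    # arbitrary ordinal grid; day values are unused for such tables
    if (anyNA(days)) days <- seq_along(samples) - 1
  }
  snv_table(ref, alt, days, site_id = dt$site_id, samples = samples)
}

#' @rdname read_snv_table
#' @param tab an [snv_table()].
#' @export
write_snv_table <- function(tab, path) {
  stopifnot(inherits(tab, "snv_table"))
  out <- data.table::data.table(site_id = tab$site_id)
  for (j in seq_along(tab$samples)) {
    s <- tab$samples[j]
    out[[paste0(s, "_ref")]] <- tab$ref[, j]
    out[[paste0(s, "_alt")]] <- tab$alt[, j]
    out[[paste0(s, "_depth")]] <- tab$depth[, j]
  }
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}
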