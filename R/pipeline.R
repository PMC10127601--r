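#' Pipeline configuration
#'
#' Collects all thresholds and module parameters for [run_pipeline()].
#' Input directory layout (as produced by [write_community()]):
#' `samples.tsv` (columns `sample`, `day`), `species_abundance.tsv`
#' (column `species` then one column per sample), one `snv_<species>.tsv`
#' per species and, optionally, `crosshost_<species>.tsv` panels used for
#' F_ST normalization (species without a panel get normalizer 1, flagged
#' in the report).
#'
#' @param input_dir directory with the input tables.
#' @param output_dir directory for all outputs (created if missing).
#' @param seed integer seed controlling every stochastic step.
#' @param min_median_depth species inclusion: median per-site depth
#'   (default 10).
#' @param min_prevalence species inclusion: fraction of samples in which
#'   the species must be present (abundance > 0; default 0.5).
#' @param min_depth per-site depth filter for diversity and frequencies.
#' @param min_cluster_size,cor_threshold strain-inference parameters, see
#'   [cluster_snv_trajectories()].
#' @param tau,n_boot,train_frac SLM parameters, see
#'   [slm_goodness_of_fit()].
#' @param n_bins AFD bins, see [fit_gamma_afd()].
#' @param alpha significance level shared by the ADF and SLM tests.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir, output_dir = file.path(input_dir, "out"),
                            seed = 1L, min_median_depth = 10,
                            min_prevalence = 0.5, min_depth = 5,
                            min_cluster_size = 1000, cor_threshold = 0.8,
                            tau = 1, n_boot = 1000,
                            train_frac = 1 / 3, n_bins = 20, alpha = 0.05) {
  thr <- c(min_median_depth = min_median_depth, min_prevalence = min_prevalence,
           min_depth = min_depth, min_cluster_size = min_cluster_size,
           cor_threshold = cor_threshold, tau = tau, n_boot = n_boot,
           n_bins = n_bins, alpha = alpha)
  if (any(thr <= 0)) stop("all thresholds must be positive")
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full strain-stability analysis over one host
#'
#' Executes, in order: species inclusion filtering; per-species diversity
#' (pi, pi_BT, F_ST, F_ST' against the first included sample, normalized
#' by the cross-host mean F_ST when a panel is available); ADF
#' stationarity classification of each F_ST' series; strain phasing and
#' strain abundance trajectories; SLM moment fits and goodness-of-fit
#' tests at strain and species level; pooled macroecology (Taylor's law,
#' gamma AFD); and the multi-strain versus singleton pass-rate
#' contingency test. All intermediate artifacts are written to
#' `output_dir` as TSV/JSON; per-species failures are quarantined with a
#' logged reason and do not stop the run. Results are deterministic given
#' the seed.
#'
#' @param config a [pipeline_config()].
#' @return the summary report (list), invisibly; also written to
#'   `summary.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  ind <- config$input_dir
  if (!file.exists(file.path(ind, "samples.tsv")) ||
      !file.exists(file.path(ind, "species_abundance.tsv"))) {
    stop("input directory is missing samples.tsv / species_abundance.tsv")
  }
  outd <- config$output_dir
  dir.create(outd, recursive = TRUE, showWarnings = FALSE)

  samples <- as.data.frame(data.table::fread(file.path(ind, "samples.tsv")))
  abdt <- as.data.frame(data.table::fread(file.path(ind, "species_abundance.tsv")))
  species_ab <- as.matrix(abdt[, samples$sample, drop = FALSE])
  rownames(species_ab) <- abdt$species
  days <- samples$day

  quarantine <- list()
  species <- rownames(species_ab)
  tabs <- list()
  for (sp in species) {
    f <- file.path(ind, paste0("snv_", sp, ".tsv"))
    if (!file.exists(f)) {
      quarantine[[sp]] <- "no SNV table"
      next
    }
    tab <- tryCatch(read_snv_table(f, days = days),
                    error = function(e) conditionMessage(e))
    if (!inherits(tab, "snv_table")) {
      quarantine[[sp]] <- paste("unreadable SNV table:", tab)
      next
    }
    med_depth <- median(tab$depth)
    prev <- mean(species_ab[sp, ] > 0)
    if (med_depth < config$min_median_depth) {
      quarantine[[sp]] <- sprintf("median depth %.1f below %g", med_depth,
                                  config$min_median_depth)
    } else if (prev < config$min_prevalence) {
      quarantine[[sp]] <- sprintf("prevalence %.2f below %g", prev,
                                  config$min_prevalence)
    } else {
      tabs[[sp]] <- tab
    }
  }
  if (length(tabs) == 0L) stop("no species passes the inclusion criteria")

  stat_rows <- list()
  strain_pops <- list()
  strain_level_species <- character()
  n_strains <- integer()
  for (sp in names(tabs)) {
    tab <- tabs[[sp]]
    panel_f <- file.path(ind, paste0("crosshost_", sp, ".tsv"))
    normalizer <- 1
    norm_src <- "none (normalizer = 1)"
    if (file.exists(panel_f)) {
      panel <- read_snv_table(panel_f, days = NULL)
      normalizer <- crosshost_mean_fst(panel, config$min_depth)
      norm_src <- "crosshost panel"
      if (!is.finite(normalizer) || normalizer <= 0) {
        normalizer <- 1
        norm_src <- "degenerate panel (normalizer = 1)"
      }
    }
    fs <- fst_series(tab, normalizer = normalizer,
                     min_depth = config$min_depth)
    data.table::fwrite(fs, file.path(outd, paste0("fst_", sp, ".tsv")),
                       sep = "\t")
    adf <- tryCatch(adf_stationarity(fs$fst_prime[-1], alpha = config$alpha),
                    error = function(e) NULL)
    stat_rows[[sp]] <- data.frame(
      species = sp,
      adf_statistic = if (is.null(adf)) NA_real_ else adf$statistic,
      p_value = if (is.null(adf)) NA_real_ else adf$p_value,
      stationary = if (is.null(adf)) NA else adf$stationary,
      n = if (is.null(adf)) NA_integer_ else adf$n,
      normalizer = normalizer, normalizer_source = norm_src,
      stringsAsFactors = FALSE)

    st <- infer_strains(tab, species_abundance = species_ab[sp, ],
                        min_cluster_size = config$min_cluster_size,
                        cor_threshold = config$cor_threshold,
                        min_depth = config$min_depth)
    n_strains[sp] <- st$n_strains
    sdt <- data.table::data.table(
      strain = rep(rownames(st$frequencies), ncol(st$frequencies)),
      day = rep(tab$days, each = nrow(st$frequencies)),
      frequency = as.vector(st$frequencies),
      abundance = as.vector(st$abundances))
    data.table::fwrite(sdt, file.path(outd, paste0("strains_", sp, ".tsv")),
                       sep = "\t")
    jsonlite::write_json(
      lapply(st$clusters, function(cl)
        list(sites = cl$sites, flip = cl$flip)),
      file.path(outd, paste0("genotypes_", sp, ".json")),
      auto_unbox = FALSE)
    for (i in seq_len(nrow(st$abundances))) {
      nmi <- paste0(sp, ".", rownames(st$abundances)[i])
      strain_pops[[nmi]] <- st$abundances[i, ]
      strain_level_species[nmi] <- sp
    }
  }
  stationarity <- do.call(rbind, stat_rows)
  data.table::fwrite(stationarity, file.path(outd, "stationarity.tsv"),
                     sep = "\t")

  species_pops <- lapply(names(tabs), function(sp) species_ab[sp, ])
  names(species_pops) <- names(tabs)
  slm_res <- rbind(
    run_slm_battery(strain_pops, days, level = "strain",
                    n_boot = config$n_boot, tau = config$tau,
                    train_frac = config$train_frac, alpha = config$alpha),
    run_slm_battery(species_pops, days, level = "species",
                    n_boot = config$n_boot, tau = config$tau,
                    train_frac = config$train_frac, alpha = config$alpha))
  data.table::fwrite(slm_res, file.path(outd, "slm_results.tsv"), sep = "\t")

  # macroecology across strains (zeros kept for moments, dropped for logs)
  macro <- tryCatch({
    tl <- fit_taylors_law(strain_pops)
    resc <- lapply(strain_pops, function(x)
      tryCatch(rescale_afd(x), error = function(e) NULL))
    resc <- Filter(Negate(is.null), resc)
    afd <- if (length(resc) >= 2) {
      fit_gamma_afd(resc, n_bins = config$n_bins)
    }
    list(alpha = tl$alpha, intercept = tl$intercept,
         n_populations = tl$n_populations,
         afd_shape = if (!is.null(afd)) afd$shape else NA,
         afd_bin_mid = if (!is.null(afd)) afd$bin_mid else NULL,
         afd_bin_means = if (!is.null(afd)) afd$bin_means else NULL)
  }, error = function(e) list(error = conditionMessage(e)))
  jsonlite::write_json(macro, file.path(outd, "macroecology.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")

  # pass-rate contingency: strains of multi-strain species vs singletons
  srows <- slm_res[slm_res$level == "strain" & slm_res$status == "ok", ]
  multi <- n_strains[strain_level_species[srows$population]] > 1
  ctab <- c(n_pass_multi = sum(srows$pass & multi),
            n_fail_multi = sum(!srows$pass & multi),
            n_pass_single = sum(srows$pass & !multi),
            n_fail_single = sum(!srows$pass & !multi))
  cont <- tryCatch(contingency_pass_rate_test(ctab[1], ctab[2], ctab[3], ctab[4]),
                   error = function(e) list(chi2 = NA, p_value = NA,
                                            note = conditionMessage(e)))

  report <- list(
    seed = config$seed,
    n_species_included = length(tabs),
    quarantined = quarantine,
    stationarity = list(n_stationary = sum(stationarity$stationary, na.rm = TRUE),
                        n_tested = sum(!is.na(stationarity$stationary))),
    n_strains = as.list(n_strains),
    slm = list(
      strain_pass = sum(srows$pass),
      strain_total = nrow(srows),
      species_pass = sum(slm_res$pass[slm_res$level == "species" &
                                        slm_res$status == "ok"]),
      species_total = sum(slm_res$level == "species" &
                            slm_res$status == "ok")),
    contingency = list(table = as.list(ctab), chi2 = cont$chi2,
                       p_value = cont$p_value),
    macroecology = macro[c("alpha", "intercept", "afd_shape")])
  jsonlite::write_json(report, file.path(outd, "summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(report)
}

#' Chi-square test of SLM pass rates: cocolonized vs singleton strains
#'
#' 2x2 chi-square test of independence, with Yates continuity correction,
#' comparing the goodness-of-fit pass rate of strains that share their
#' species with another strain against singly colonizing strains.
#'
#' @param n_pass_multi,n_fail_multi pass/fail counts among strains with a
#'   conspecific strain present.
#' @param n_pass_single,n_fail_single pass/fail counts among singly
#'   colonizing strains.
#' @return list with `chi2`, `p_value` and the 2x2 `table`.
#' @examples
#' contingency_pass_rate_test(24, 8, 25, 5)  # chi2 ~ 0.24, p ~ 0.62
#' @export
contingency_pass_rate_test <- function(n_pass_multi, n_fail_multi,
                                       n_pass_single, n_fail_single) {
  counts <- c(n_pass_multi, n_fail_multi, n_pass_single, n_fail_single)
  if (any(counts < 0)) stop("counts must be non-negative")
  tab <- matrix(counts, nrow = 2, byrow = TRUE,
                dimnames = list(c("multi", "single"), c("pass", "fail")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("contingency table has an empty row or column")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
  list(chi2 = unname(ct$statistic), p_value = ct$p.value, table = tab)
}
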