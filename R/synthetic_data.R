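#' Configuration for a synthetic strain community
#'
#' Describes the ground truth used by [simulate_strain_community()]: a
#' host carrying `n_species` species, each colonized by 1 to 4 conspecific
#' strains whose abundances follow independent stochastic logistic
#' dynamics around fixed carrying capacities. Strain pairs are separated
#' by thousands of fixed SNV differences; read sampling is binomial at
#' depths coupled to species abundance, and samples are taken on an
#' irregular daily-to-weekly grid as in dense gut time series (median gap
#' 1-2 days).
#'
#' @param n_species number of species in the host.
#' @param strains_per_species integer vector in 1..4 (recycled across
#'   species).
#' @param n_fixed_diffs fixed-difference sites carried by each
#'   non-background strain (so any strain differs from the background
#'   haplotype at `n_fixed_diffs` sites, and two marker strains at twice
#'   that). Typical real scale: 1e3-1e4.
#' @param n_monomorphic invariant sites per species (genome backdrop).
#' @param n_timepoints number of samples if `day_grid` is not given.
#' @param day_grid optional strictly increasing integer days; if `NULL`,
#'   gaps are drawn from `gap_choices` with `gap_weights`.
#' @param gap_choices,gap_weights distribution of day gaps (defaults
#'   `c(1, 2, 3, 7)` with weights `c(0.45, 0.35, 0.15, 0.05)`, matching a
#'   median sampling interval of 1-2 days).
#' @param mean_depth target mean per-site read depth for each species.
#' @param slm_params optional list (one element per species) of lists with
#'   numeric vectors `K`, `sigma`, `tau` (one entry per strain). If
#'   `NULL`, carrying capacities are drawn log-uniformly from
#'   `c(0.005, 0.05)` with `sigma = 0.5` and `tau = 1` day.
#' @param background_K,background_sigma SLM parameters of the unmodelled
#'   remainder of the community that closes the composition; default
#'   `background_K = max(0.2, 1 - sum(K))`.
#' @param replacement_events optional list of events, each a list with
#'   `species` (index), `strain` (index), `start_day`, `duration` (days)
#'   and `final_freq`: the strain's within-species frequency is ramped
#'   logistically from its value at `start_day` to `final_freq` over
#'   `duration`, with the other strains rescaled proportionally -
#'   emulating a strain-replacement episode.
#' @param within_strain_noise standard deviation of optional per-site
#'   frequency jitter (default 0: strains are internally monomorphic).
#' @param seed integer RNG seed; seeded runs are bit-reproducible.
#' @return validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_species = 2,
                             strains_per_species = c(2, 1),
                             n_fixed_diffs = 1500,
                             n_monomorphic = 500,
                             n_timepoints = 90,
                             day_grid = NULL,
                             gap_choices = c(1, 2, 3, 7),
                             gap_weights = c(0.45, 0.35, 0.15, 0.05),
                             mean_depth = 50,
                             slm_params = NULL,
                             background_K = NULL,
                             background_sigma = 0.3,
                             replacement_events = NULL,
                             within_strain_noise = 0,
                             seed = 1L) {
  strains_per_species <- rep_len(as.integer(strains_per_species), n_species)
  if (any(strains_per_species < 1L | strains_per_species > 4L)) {
    stop("`strains_per_species` must lie in 1..4")
  }
  if (!is.null(day_grid)) {
    if (any(diff(day_grid) <= 0)) stop("`day_grid` must be strictly increasing")
    n_timepoints <- length(day_grid)
  }
  if (!is.null(slm_params)) {
    if (length(slm_params) != n_species) {
      stop("`slm_params` must have one element per species")
    }
    for (s in seq_len(n_species)) {
      p <- slm_params[[s]]
      if (length(p$K) != strains_per_species[s]) {
        stop("species ", s, ": need one K per strain")
      }
      if (any(p$K <= 0)) stop("all K must be > 0")
      if (any(p$sigma < 0 | p$sigma >= 2)) stop("sigma must lie in [0, 2)")
      if (any(p$tau <= 0)) stop("tau must be > 0")
    }
  }
  if (n_fixed_diffs < 1) stop("`n_fixed_diffs` must be >= 1")
  if (mean_depth <= 0) stop("`mean_depth` must be positive")
  structure(list(n_species = n_species,
                 strains_per_species = strains_per_species,
                 n_fixed_diffs = as.integer(n_fixed_diffs),
                 n_monomorphic = as.integer(n_monomorphic),
                 n_timepoints = as.integer(n_timepoints),
                 day_grid = day_grid, gap_choices = gap_choices,
                 gap_weights = gap_weights, mean_depth = mean_depth,
                 slm_params = slm_params, background_K = background_K,
                 background_sigma = background_sigma,
                 replacement_events = replacement_events,
                 within_strain_noise = within_strain_noise,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Simulate a host's strain community with known ground truth
#'
#' Generates, for one host: per-species SNV time-series tables
#' ([snv_table()]), a species relative-abundance table and the full
#' ground truth (strain frequency and abundance trajectories, SNV-to-
#' strain assignments with polarities, SLM parameters). Strain abundances
#' follow independent SLM trajectories; species relative abundance is the
#' strain sum renormalized over all species plus an unmodelled background
#' component; each non-background strain carries `n_fixed_diffs` marker
#' sites whose alternate-allele labelling is randomized per site (so
#' roughly half the observed trajectories are mirror images, exercising
#' polarization); per-site depths are Poisson with intensity proportional
#' to the species' relative abundance (scaled to hit `mean_depth` on
#' average), and observed alternate counts are binomial at the true
#' site frequency.
#'
#' @param config a [synthetic_config()].
#' @return list with `snv_tables` (named list of [snv_table()]),
#'   `species_abundance` (species x samples matrix), `samples`
#'   (data.frame `sample`, `day`) and `truth` (list with per-species
#'   `strain_freqs`, `strain_abundances` matrices, `assignments`
#'   data.frame with site/strain/flip, and `params`).
#' @export
simulate_strain_community <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  nT <- config$n_timepoints
  days <- config$day_grid
  if (is.null(days)) {
    gaps <- sample(config$gap_choices, nT - 1, replace = TRUE,
                   prob = config$gap_weights)
    days <- cumsum(c(0, gaps))
  }
  nsp <- config$n_species
  kvec <- config$strains_per_species
  params <- config$slm_params
  if (is.null(params)) {
    params <- lapply(seq_len(nsp), function(s) {
      k <- kvec[s]
      list(K = exp(runif(k, log(0.005), log(0.05))),
           sigma = rep(0.5, k), tau = rep(1, k))
    })
  }

  # strain abundance paths (started at stationarity) + background closure
  strain_x <- vector("list", nsp)
  for (s in seq_len(nsp)) {
    p <- params[[s]]
    x0 <- mapply(function(K, sg) {
      if (sg > 0) rstationary_gamma(1, K, sg) else K
    }, p$K, p$sigma)
    strain_x[[s]] <- matrix(
      simulate_slm_trajectory(days, x0 = x0, K = p$K, sigma = p$sigma,
                              tau = p$tau, n_paths = kvec[s]),
      nrow = kvec[s])
  }
  ktot <- sum(vapply(params, function(p) sum(p$K), numeric(1)))
  bgK <- if (is.null(config$background_K)) max(0.2, 1 - ktot) else config$background_K
  bg <- simulate_slm_trajectory(days, x0 = rstationary_gamma(1, bgK, config$background_sigma),
                                K = bgK, sigma = config$background_sigma)
  total <- Reduce(`+`, lapply(strain_x, colSums)) + bg

  species_abund <- do.call(rbind, lapply(strain_x, function(m) colSums(m) / total))
  rownames(species_abund) <- paste0("species_", seq_len(nsp))

  strain_freqs <- lapply(seq_len(nsp), function(s)
    sweep(strain_x[[s]], 2, colSums(strain_x[[s]]), "/"))

  # replacement events act on within-species frequencies
  for (ev in config$replacement_events) {
    s <- ev$species
    fr <- strain_freqs[[s]]
    i <- ev$strain
    f0 <- fr[i, max(which(days <= ev$start_day))]
    mid <- ev$start_day + ev$duration / 2
    ramp <- 1 / (1 + exp(-(days - mid) / (ev$duration / 8)))
    ramp[days < ev$start_day] <- 0
    target <- f0 + (ev$final_freq - f0) * ramp
    scale <- (1 - target) / pmax(1 - fr[i, ], 1e-12)
    fr <- sweep(fr, 2, scale, "*")
    fr[i, ] <- target
    strain_freqs[[s]] <- sweep(fr, 2, colSums(fr), "/")
  }
  strain_ab <- lapply(seq_len(nsp), function(s)
    sweep(strain_freqs[[s]], 2, species_abund[s, ], "*"))

  # observed SNV tables
  snv_tables <- vector("list", nsp)
  assignments <- vector("list", nsp)
  for (s in seq_len(nsp)) {
    k <- kvec[s]
    n_marker <- (k - 1) * config$n_fixed_diffs
    n_sites <- n_marker + config$n_monomorphic
    carrier <- c(rep(seq_len(max(k - 1, 0)), each = config$n_fixed_diffs),
                 rep(NA_integer_, config$n_monomorphic))
    if (k == 1L) carrier <- rep(NA_integer_, n_sites <- config$n_monomorphic)
    flip <- runif(length(carrier)) < 0.5
    fr <- strain_freqs[[s]]
    p_site <- matrix(0, length(carrier), nT)
    has <- !is.na(carrier)
    if (any(has)) p_site[has, ] <- fr[carrier[has], , drop = FALSE]
    p_site[flip, ] <- 1 - p_site[flip, ]
    if (config$within_strain_noise > 0) {
      p_site <- p_site + rnorm(length(p_site), sd = config$within_strain_noise)
      p_site <- pmin(pmax(p_site, 0), 1)
    }
    lam <- config$mean_depth * species_abund[s, ] / mean(species_abund[s, ])
    depth <- matrix(rpois(length(carrier) * nT, rep(lam, each = length(carrier))),
                    nrow = length(carrier))
    altc <- matrix(rbinom(length(depth), as.vector(depth), as.vector(p_site)),
                   nrow = nrow(depth))
    site_id <- sprintf("s%d_site_%05d", s, seq_along(carrier))
    snv_tables[[s]] <- snv_table(depth - altc, altc, days, site_id = site_id)
    assignments[[s]] <- data.frame(site_id = site_id,
                                   species = rownames(species_abund)[s],
                                   strain = carrier, flip = flip,
                                   stringsAsFactors = FALSE)
    rownames(strain_freqs[[s]]) <- rownames(strain_ab[[s]]) <-
      paste0("strain_", seq_len(k))
  }
  names(snv_tables) <- names(strain_freqs) <- names(strain_ab) <-
    rownames(species_abund)
  samples <- data.frame(sample = snv_tables[[1]]$samples, day = days,
                        stringsAsFactors = FALSE)
  colnames(species_abund) <- samples$sample

  list(snv_tables = snv_tables,
       species_abundance = species_abund,
       samples = samples,
       truth = list(strain_freqs = strain_freqs,
                    strain_abundances = strain_ab,
                    species_abundance = species_abund,
                    assignments = do.call(rbind, assignments),
                    params = params,
                    background = list(K = bgK, sigma = config$background_sigma),
                    days = days, seed = config$seed))
}

#' Multinomial compositional sampling panel
#'
#' Draws repeated multinomial samples of `n_reads` reads over populations
#' with fixed true relative abundances, emulating a community whose only
#' temporal variability is compositional sampling noise. If the supplied
#' means sum to less than 1, an implicit remainder category absorbs the
#' rest of the reads and is dropped from the output.
#'
#' @param true_means per-population true relative abundances; must sum to
#'   at most 1.
#' @param n_reads reads per sample.
#' @param n_samples number of independent samples (time points).
#' @return matrix (populations x samples) of observed relative abundances
#'   `counts / n_reads`.
#' @export
simulate_multinomial_panel <- function(true_means, n_reads, n_samples) {
  if (any(true_means < 0)) stop("`true_means` must be non-negative")
  tot <- sum(true_means)
  if (tot > 1 + 1e-8) stop("`true_means` must sum to at most 1")
  if (n_reads < 1 || n_samples < 1) stop("`n_reads` and `n_samples` must be positive")
  probs <- c(true_means, max(1 - tot, 0))
  counts <- rmultinom(n_samples, size = n_reads, prob = probs)
  out <- counts[seq_along(true_means), , drop = FALSE] / n_reads
  rownames(out) <- names(true_means)
  out
}

#' Simulate a cross-host SNV panel for one species
#'
#' Generates single samples of the same species from `n_hosts` unrelated
#' hosts, each colonized by the species' strains at independent
#' Dirichlet-distributed frequencies, using the site/polarity map of a
#' community simulation. The resulting [snv_table()] (samples = hosts)
#' feeds [crosshost_mean_fst()] to put intra-host F_ST trajectories on
#' the between-host scale.
#'
#' @param sim result of [simulate_strain_community()].
#' @param species species name (or index) within `sim`.
#' @param n_hosts number of hosts in the panel.
#' @param mean_depth mean per-site depth in the panel samples.
#' @param concentration Dirichlet concentration of per-host strain
#'   frequencies (small values give hosts dominated by single strains, as
#'   observed across real hosts; default 0.5).
#' @return an [snv_table()] with one sample per host.
#' @export
simulate_crosshost_panel <- function(sim, species = 1, n_hosts = 20,
                                     mean_depth = 50, concentration = 0.5) {
  if (n_hosts < 2) stop("need at least 2 hosts")
  spn <- if (is.character(species)) species else rownames(sim$species_abundance)[species]
  asn <- sim$truth$assignments
  asn <- asn[asn$species == spn, , drop = FALSE]
  k <- nrow(sim$truth$strain_freqs[[spn]])
  g <- matrix(rgamma(n_hosts * k, shape = concentration), nrow = k)
  hostfreq <- sweep(g, 2, colSums(g), "/")
  p <- matrix(0, nrow(asn), n_hosts)
  has <- !is.na(asn$strain)
  if (any(has)) p[has, ] <- hostfreq[asn$strain[has], , drop = FALSE]
  p[asn$flip, ] <- 1 - p[asn$flip, ]
  depth <- matrix(rpois(nrow(asn) * n_hosts, mean_depth), nrow = nrow(asn))
  altc <- matrix(rbinom(length(depth), as.vector(depth), as.vector(p)),
                 nrow = nrow(depth))
  snv_table(depth - altc, altc, days = seq_len(n_hosts) - 1,
            site_id = asn$site_id,
            samples = paste0("host_", seq_len(n_hosts)))
}

#' Write a simulated community in the pipeline's input layout
#'
#' Emits `samples.tsv` (sample, day), `species_abundance.tsv` (species x
#' samples), one `snv_<species>.tsv` per species, a `truth.json` with the
#' ground-truth trajectories and assignments, and (optionally) one
#' `crosshost_<species>.tsv` panel per species for F_ST normalization.
#'
#' @param sim result of [simulate_strain_community()].
#' @param dir output directory (created if missing).
#' @param crosshost_hosts if > 0, also write a simulated cross-host panel
#'   of this many hosts for each species.
#' @param mean_depth panel depth, passed to [simulate_crosshost_panel()].
#' @return `dir`, invisibly.
#' @export
write_community <- function(sim, dir, crosshost_hosts = 0, mean_depth = 50) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(sim$samples, file.path(dir, "samples.tsv"), sep = "\t")
  ab <- data.table::data.table(species = rownames(sim$species_abundance))
  for (j in seq_len(ncol(sim$species_abundance))) {
    ab[[colnames(sim$species_abundance)[j]]] <- sim$species_abundance[, j]
  }
  data.table::fwrite(ab, file.path(dir, "species_abundance.tsv"), sep = "\t")
  for (sp in names(sim$snv_tables)) {
    write_snv_table(sim$snv_tables[[sp]], file.path(dir, paste0("snv_", sp, ".tsv")))
    if (crosshost_hosts > 0) {
      panel <- simulate_crosshost_panel(sim, sp, n_hosts = crosshost_hosts,
                                        mean_depth = mean_depth)
      write_snv_table(panel, file.path(dir, paste0("crosshost_", sp, ".tsv")))
    }
  }
  truth <- sim$truth
  truth$strain_freqs <- lapply(truth$strain_freqs, unname)
  truth$strain_abundances <- lapply(truth$strain_abundances, unname)
  truth$species_abundance <- unname(truth$species_abundance)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
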