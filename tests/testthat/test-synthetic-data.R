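test_that("config validation enforces the model's parameter ranges", {
  expect_error(synthetic_config(strains_per_species = 5), "1..4")
  expect_error(synthetic_config(day_grid = c(0, 2, 2)), "increasing")
  expect_error(synthetic_config(
    n_species = 1, strains_per_species = 2,
    slm_params = list(list(K = c(0.1, -1), sigma = c(0.5, 0.5),
                           tau = c(1, 1)))), "K")
  expect_error(synthetic_config(
    n_species = 1, strains_per_species = 1,
    slm_params = list(list(K = 0.1, sigma = 2, tau = 1))), "sigma")
})

test_that("true strain frequencies sum to one and abundances close the species", {
  sim <- toy_community(k = 3, depth = 30, seed = 91, n_timepoints = 50)
  fr <- sim$truth$strain_freqs[[1]]
  expect_equal(colSums(fr), rep(1, 50), tolerance = 1e-12)
  expect_true(all(fr >= 0 & fr <= 1))
  ab <- sim$truth$strain_abundances[[1]]
  expect_equal(colSums(ab), unname(sim$species_abundance[1, ]),
               tolerance = 1e-12)
  expect_true(all(diff(sim$samples$day) > 0))
  # marker sites partition: each non-background strain carries its block
  asn <- sim$truth$assignments
  expect_identical(sum(!is.na(asn$strain)), 2L * 1500L)
})

test_that("seeded community simulations are bit-reproducible", {
  a <- toy_community(k = 2, depth = 40, seed = 92, n_timepoints = 30)
  b <- toy_community(k = 2, depth = 40, seed = 92, n_timepoints = 30)
  expect_identical(a$snv_tables[[1]]$alt, b$snv_tables[[1]]$alt)
  expect_identical(a$species_abundance, b$species_abundance)
  expect_identical(a$truth$strain_freqs, b$truth$strain_freqs)
})

test_that("observed site frequencies are binomial around constant strain freqs", {
  # two strains frozen at 0.6/0.4 (sigma = 0), depth 50: per-site alternate
  # frequencies at polarity-consistent sites are ~0.4 with binomial sd
  cfg <- synthetic_config(
    n_species = 1, strains_per_species = 2, n_fixed_diffs = 2000,
    n_monomorphic = 0, n_timepoints = 40, mean_depth = 50,
    slm_params = list(list(K = c(0.06, 0.04), sigma = c(0, 0), tau = c(1, 1))),
    seed = 93)
  sim <- simulate_strain_community(cfg)
  expect_equal(unname(sim$truth$strain_freqs[[1]][1, 1]), 0.6)
  tab <- sim$snv_tables[[1]]
  # marker sites are carried by strain 1 (frequency 0.6); after undoing
  # the per-site polarity, observed frequencies are ~0.6 with binomial sd
  f <- allele_frequencies(tab, min_depth = 1)
  flip <- sim$truth$assignments$flip
  f[flip, ] <- 1 - f[flip, ]
  expect_equal(mean(f, na.rm = TRUE), 0.6, tolerance = 0.01)
  d <- mean(tab$depth)
  expect_equal(sd(f - 0.6, na.rm = TRUE), sqrt(0.4 * 0.6 / d),
               tolerance = 0.1)
  # roughly half the sites have randomized polarity
  expect_equal(mean(flip), 0.5, tolerance = 0.05)
})

test_that("read depth tracks species abundance at the requested mean", {
  sim <- toy_community(k = 2, depth = 35, seed = 94, n_timepoints = 60)
  tab <- sim$snv_tables[[1]]
  expect_equal(mean(tab$depth), 35, tolerance = 0.05)
  ab <- sim$species_abundance[1, ]
  expect_gt(cor(colMeans(tab$depth), ab), 0.95)
})

test_that("multinomial panel: degenerate, variance and mean contracts", {
  set.seed(95)
  one <- simulate_multinomial_panel(1, 1000, 20)
  expect_true(all(one == 1))
  means <- 10^seq(-4, -1, length.out = 100)
  means <- means / sum(means)
  panel <- simulate_multinomial_panel(means, 1e5, 100)
  expect_equal(unname(rowMeans(panel)), means, tolerance = 0.2)
  v <- apply(panel, 1, var)
  expect_equal(median(v / (means * (1 - means) / 1e5)), 1, tolerance = 0.2)
  expect_error(simulate_multinomial_panel(c(0.9, 0.3), 10, 10), "at most 1")
  expect_error(simulate_multinomial_panel(-0.1, 10, 10), "non-negative")
})

test_that("a replacement event reshapes frequencies toward the target", {
  d <- seq(0, 150, by = 2)
  cfg <- synthetic_config(
    n_species = 1, strains_per_species = 2, n_fixed_diffs = 100,
    n_monomorphic = 0, day_grid = d,
    slm_params = list(list(K = c(0.05, 0.01), sigma = c(0.3, 0.3),
                           tau = c(1, 1))),
    replacement_events = list(list(species = 1, strain = 2, start_day = 40,
                                   duration = 60, final_freq = 0.9)),
    seed = 96)
  sim <- simulate_strain_community(cfg)
  fr <- sim$truth$strain_freqs[[1]]
  expect_lt(fr[2, 1], 0.3)                      # initially rare
  expect_gt(fr[2, length(d)], 0.85)             # dominant at the end
  expect_equal(colSums(fr), rep(1, length(d)), tolerance = 1e-12)
})

test_that("cross-host panels give a usable F_ST normalizer", {
  sim <- toy_community(k = 2, depth = 50, seed = 97, n_timepoints = 30,
                       n_fixed = 800)
  set.seed(97)
  panel <- simulate_crosshost_panel(sim, 1, n_hosts = 20, mean_depth = 50)
  expect_s3_class(panel, "snv_table")
  expect_identical(ncol(panel$ref), 20L)
  norm <- crosshost_mean_fst(panel)
  expect_gt(norm, 0.05)  # unrelated hosts are strongly differentiated
  expect_lt(norm, 1)
})
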