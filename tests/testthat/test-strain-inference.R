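test_that("polarize_trajectory aligns identity, mirror and degenerate cases", {
  centroid <- c(0.2, 0.5, 0.8, 0.4)
  same <- polarize_trajectory(centroid, centroid)
  expect_false(same$flip)
  expect_equal(same$aligned, centroid)
  mir <- polarize_trajectory(1 - centroid, centroid)
  expect_true(mir$flip)
  expect_equal(mir$aligned, centroid)
  flat <- polarize_trajectory(rep(0.5, 4), centroid)
  expect_true(is.na(flat$flip))
  expect_error(polarize_trajectory(c(0.1, NA, NA, NA), centroid), "finite")
})

test_that("a single-strain species yields no clusters and one strain", {
  sim <- toy_community(k = 1, depth = 50, seed = 51, n_timepoints = 40)
  tab <- sim$snv_tables[[1]]
  cl <- cluster_snv_trajectories(tab)
  expect_length(cl, 0)
  st <- infer_strains(tab, species_abundance = sim$species_abundance[1, ])
  expect_identical(st$n_strains, 1L)
  expect_equal(unname(st$frequencies[1, ]), rep(1, 40))
  expect_equal(unname(st$abundances[1, ]), unname(sim$species_abundance[1, ]))
  # all-monomorphic table -> downstream pi is 0 as well
  expect_equal(max(compute_pi(tab)), 0, tolerance = 1e-3)
})

test_that("a two-strain species is recovered with a large, accurate cluster", {
  sim <- toy_community(k = 2, depth = 50, seed = 52)
  tab <- sim$snv_tables[[1]]
  cl <- cluster_snv_trajectories(tab)
  expect_length(cl, 1)
  expect_gt(length(cl[[1]]$sites), 1000)
  truth <- sim$truth$strain_freqs[[1]]
  expect_gt(max(abs(cor(cl[[1]]$centroid, t(truth)))), 0.99)
  st <- infer_strains(tab, species_abundance = sim$species_abundance[1, ])
  expect_identical(st$n_strains, 2L)
  expect_true(all(match_cors(st$frequencies, truth) > 0.99))
  # cluster recall: fraction of true fixed-difference sites recovered
  truth_sites <- subset(sim$truth$assignments, !is.na(strain))$site_id
  expect_gt(mean(truth_sites %in% cl[[1]]$sites), 0.95)
})

test_that("a three-strain species yields two clusters and three trajectories", {
  sim <- toy_community(k = 3, depth = 50, seed = 53)
  st <- infer_strains(sim$snv_tables[[1]],
                      species_abundance = sim$species_abundance[1, ])
  expect_length(st$clusters, 2)
  expect_identical(st$n_strains, 3L)
  expect_true(all(match_cors(st$frequencies,
                             sim$truth$strain_freqs[[1]]) > 0.99))
})

test_that("clustering is invariant to site order and ref/alt label flips", {
  sim <- toy_community(k = 2, depth = 50, seed = 54, n_fixed = 1100,
                       n_timepoints = 60)
  tab <- sim$snv_tables[[1]]
  base <- cluster_snv_trajectories(tab)
  # shuffle site order
  set.seed(1)
  perm <- sample(nrow(tab$ref))
  shuf <- snv_table(tab$ref[perm, ], tab$alt[perm, ], tab$days,
                    site_id = tab$site_id[perm])
  cl_shuf <- cluster_snv_trajectories(shuf)
  expect_length(cl_shuf, length(base))
  expect_setequal(cl_shuf[[1]]$sites, base[[1]]$sites)
  # flip ref/alt at a random subset of sites
  flip <- runif(nrow(tab$ref)) < 0.5
  ref2 <- tab$ref; alt2 <- tab$alt
  ref2[flip, ] <- tab$alt[flip, ]
  alt2[flip, ] <- tab$ref[flip, ]
  cl_flip <- cluster_snv_trajectories(
    snv_table(ref2, alt2, tab$days, site_id = tab$site_id))
  expect_setequal(cl_flip[[1]]$sites, base[[1]]$sites)
  # with a single cluster the orientation is only defined up to mirror
  dev <- min(max(abs(cl_flip[[1]]$centroid - base[[1]]$centroid)),
             max(abs(cl_flip[[1]]$centroid - (1 - base[[1]]$centroid))))
  expect_lt(dev, 1e-8)
})

test_that("strain frequencies are a renormalized complement of the centroids", {
  days <- 0:9
  tab <- snv_table(matrix(10, 2, 10), matrix(10, 2, 10), days)
  mk <- function(f) list(sites = "x", flip = FALSE, centroid = rep(f, 10))
  # one cluster at 0.4 -> strains at 0.4 / 0.6
  fr <- strain_frequencies(list(mk(0.4)), tab)
  expect_equal(unname(fr[, 1]), c(0.4, 0.6))
  # two centroids 0.5 and 0.3 -> third strain at 0.2
  fr3 <- strain_frequencies(list(mk(0.5), mk(0.3)), tab)
  expect_equal(unname(fr3[, 1]), c(0.5, 0.3, 0.2))
  expect_equal(colSums(fr3), rep(1, 10))
  # centroid sums above 1.1 raise the mis-clustering warning
  expect_warning(strain_frequencies(list(mk(0.7), mk(0.6)), tab), "1.1")
})

test_that("inferred frequencies always sum to one at every time point", {
  for (seed in c(55, 56)) {
    sim <- toy_community(k = sample(2:3, 1), depth = 30, seed = seed,
                         n_timepoints = 60)
    st <- infer_strains(sim$snv_tables[[1]])
    expect_equal(colSums(st$frequencies), rep(1, 60), tolerance = 1e-12)
    expect_true(all(st$frequencies >= 0 & st$frequencies <= 1))
  }
})

test_that("strain abundances are the frequency-by-species-abundance product", {
  fr <- matrix(c(0.6, 0.4), 2, 1)
  attr(fr, "days") <- 0
  ab <- strain_abundances(fr, 0.05)
  expect_equal(unname(ab[, 1]), c(0.03, 0.02))
  expect_error(strain_abundances(fr, c(0.05, 0.1)), "day grid")
  sim <- toy_community(k = 2, depth = 50, seed = 57, n_timepoints = 60)
  st <- infer_strains(sim$snv_tables[[1]],
                      species_abundance = sim$species_abundance[1, ])
  expect_equal(colSums(st$abundances), unname(sim$species_abundance[1, ]))
  # recovered abundances track the truth closely
  tr_ab <- sim$truth$strain_abundances[[1]]
  expect_true(all(match_cors(st$abundances, tr_ab) > 0.95))
})
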