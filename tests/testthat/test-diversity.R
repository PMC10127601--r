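test_that("monomorphic sites give zero diversity", {
  tab <- snv_table(ref = matrix(20, 5, 2), alt = matrix(0, 5, 2),
                   days = c(0, 3))
  expect_equal(as.numeric(compute_pi(tab, 1)), 0)
  expect_equal(as.numeric(compute_pi_between(tab, 1, 2)), 0)
  expect_true(is.na(compute_fst(tab, 1, 2)))  # pi_BT = 0 is undefined F_ST
})

test_that("hand-computed worked values for one site with r = a = 5, d = 10", {
  tab <- toy_half_table()
  expect_equal(as.numeric(compute_pi(tab, 1)), 2 * 0.5 * 5 / 9)  # 0.5555...
  expect_equal(as.numeric(compute_pi_between(tab, 1, 2)), 0.5)
  expect_equal(compute_fst(tab, 1, 2), (0.5 - 5 / 9) / 0.5)      # -0.111...
})

test_that("fully differentiated samples have pi_BT = 1 and F_ST = 1", {
  tab <- snv_table(ref = cbind(30, 0), alt = cbind(0, 30), days = c(0, 1))
  expect_equal(as.numeric(compute_pi_between(tab, 1, 2)), 1)
  expect_equal(compute_fst(tab, 1, 2), 1)
})

test_that("low-depth sites are excluded from the |G| denominator", {
  # site 1 polymorphic at depth 4 (below 5x): must be dropped entirely
  tab <- snv_table(ref = rbind(c(2, 2), c(10, 10)),
                   alt = rbind(c(2, 2), c(10, 10)), days = c(0, 1))
  pi1 <- compute_pi(tab, 1)
  expect_equal(attr(pi1, "n_sites"), 1L)
  expect_equal(as.numeric(pi1), 2 * 0.5 * 10 / 19)
  # no site passes -> undefined
  tab2 <- snv_table(ref = cbind(2), alt = cbind(1), days = 0)
  expect_true(is.na(compute_pi(tab2, 1)))
})

test_that("pi and pi_BT are invariant to a global ref/alt label swap", {
  set.seed(21)
  d <- matrix(rpois(20, 30), 10, 2)
  a <- matrix(rbinom(20, as.vector(d), 0.3), 10, 2)
  tab <- snv_table(d - a, a, days = c(0, 1))
  swapped <- snv_table(a, d - a, days = c(0, 1))
  expect_equal(compute_pi(tab), compute_pi(swapped))
  expect_equal(as.numeric(compute_pi_between(tab, 1, 2)),
               as.numeric(compute_pi_between(swapped, 1, 2)))
})

test_that("vectorized estimators equal the per-site brute-force average", {
  set.seed(22)
  for (rep in 1:5) {
    n <- sample(3:10, 1)
    d <- matrix(rpois(2 * n, 25) + 5, n, 2)
    a <- matrix(rbinom(2 * n, as.vector(d), runif(1, 0.1, 0.9)), n, 2)
    tab <- snv_table(d - a, a, days = c(0, 7))
    # site-by-site oracle for pi (sample 1) and pi_BT
    terms_pi <- sapply(seq_len(n), function(i) {
      r <- d[i, 1] - a[i, 1]
      (r / d[i, 1]) * (a[i, 1] / (d[i, 1] - 1)) +
        (a[i, 1] / d[i, 1]) * (r / (d[i, 1] - 1))
    })
    terms_bt <- sapply(seq_len(n), function(i) {
      f1 <- a[i, 1] / d[i, 1]; f2 <- a[i, 2] / d[i, 2]
      (1 - f1) * f2 + f1 * (1 - f2)
    })
    expect_equal(as.numeric(compute_pi(tab, 1)), mean(terms_pi))
    expect_equal(as.numeric(compute_pi_between(tab, 1, 2)), mean(terms_bt))
    expect_equal(compute_fst(tab, 1, 2),
                 (mean(terms_bt) - (as.numeric(compute_pi(tab, 1)) +
                                      as.numeric(compute_pi(tab, 2))) / 2) /
                   mean(terms_bt))
  }
})

test_that("pi_BT of a sample with itself approaches pi as depth grows", {
  set.seed(23)
  for (d0 in c(50, 500, 5000)) {
    d <- matrix(d0, 20, 2)
    a <- matrix(rep(rbinom(20, d0, 0.4), 2), 20, 2)
    tab <- snv_table(d - a, a, days = c(0, 1))
    rel <- abs(as.numeric(compute_pi_between(tab, 1, 1)) -
                 as.numeric(compute_pi(tab, 1))) /
      as.numeric(compute_pi(tab, 1))
    expect_lt(rel, 2 / d0)  # relative difference is O(1/d)
  }
})

test_that("F_ST' normalization behaves and validates", {
  expect_equal(normalize_fst(0.2, 0.2), 1)
  expect_equal(normalize_fst(c(0.1, 0.3), 0.2), c(0.5, 1.5))
  expect_error(normalize_fst(0.1, 0), "positive")
  expect_error(normalize_fst(0.1, -2), "positive")
})

test_that("cross-host mean F_ST matches the brute-force pair average", {
  set.seed(24)
  # 3 hosts with different strain mixtures over 200 shared sites
  freqs <- c(0.1, 0.5, 0.9)
  d <- matrix(rpois(600, 40) + 5, 200, 3)
  a <- sapply(1:3, function(j) rbinom(200, d[, j], freqs[j]))
  tab <- snv_table(d - a, a, days = 0:2)
  manual <- mean(c(compute_fst(tab, 1, 2), compute_fst(tab, 1, 3),
                   compute_fst(tab, 2, 3)))
  expect_equal(crosshost_mean_fst(tab), manual)
  # two hosts fixed for opposite alleles -> mean F_ST = 1
  opp <- snv_table(cbind(30, 0), cbind(0, 30), days = 0:1)
  expect_equal(crosshost_mean_fst(opp), 1)
  expect_error(crosshost_mean_fst(snv_table(cbind(5), cbind(5), days = 0)),
               "2 hosts")
})

test_that("fst_series is computed against the baseline and scales by the normalizer", {
  set.seed(25)
  sim <- toy_community(k = 2, depth = 40, seed = 61, n_timepoints = 40)
  fs <- fst_series(sim$snv_tables[[1]], normalizer = 0.5)
  expect_equal(nrow(fs), 40)
  expect_equal(fs$fst_prime, fs$fst / 0.5)
  expect_equal(attr(fs, "denominator"), "sites_passing_depth_filter")
  expect_true(all(fs$fst[-1] <= 1, na.rm = TRUE))
  expect_error(fst_series(sim$snv_tables[[1]], normalizer = 0), "positive")
})
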