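# shared fixture builders for the test suite

# one-site table with r = a = 5, d = 10 in both samples (hand-computable
# diversity values)
toy_half_table <- function() {
  snv_table(ref = matrix(5, 1, 2), alt = matrix(5, 1, 2), days = c(0, 1))
}

# irregular day grid with the generator's gap distribution
toy_days <- function(n = 90) {
  cumsum(c(0, sample(c(1, 2, 3, 7), n - 1, TRUE, c(.45, .35, .15, .05))))
}

# a k-strain single-species community with balanced carrying capacities
toy_community <- function(k = 2, depth = 50, seed = 1, n_fixed = 1500,
                          n_timepoints = 90, sigma = 0.5, ...) {
  Ks <- list(`1` = 0.04, `2` = c(0.03, 0.02), `3` = c(0.035, 0.025, 0.02))
  K <- Ks[[as.character(k)]]
  cfg <- synthetic_config(
    n_species = 1, strains_per_species = k, n_fixed_diffs = n_fixed,
    n_monomorphic = 300, n_timepoints = n_timepoints, mean_depth = depth,
    slm_params = list(list(K = K, sigma = rep(sigma, k), tau = rep(1, k))),
    seed = seed, ...)
  simulate_strain_community(cfg)
}

# best |cor| match of each inferred strain frequency to any true strain
match_cors <- function(inferred, truth) {
  vapply(seq_len(nrow(inferred)), function(i)
    max(abs(suppressWarnings(cor(inferred[i, ], t(truth))))), numeric(1))
}
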