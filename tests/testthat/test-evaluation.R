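test_that("empirical distributions are normalized frequencies", {
  tr <- structure(list(states = matrix(c(1L, 1L, 1L, 0L), 4, 2), times = 1:4,
                       subset = c(3L, 8L)), class = "state_trace")
  # rows: (1,1) (1,1)... states column-major: col1 = c(1,1,1,0), col2 = ?
  tr$states <- rbind(c(1L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 0L))
  d <- empirical_distribution(tr)
  expect_equal(d$probs, c(0, 0.75, 0.25, 0))
  expect_equal(sum(d$probs), 1)
  delta <- tr
  delta$states <- matrix(rep(c(1L, 1L), each = 5), 5, 2)
  expect_equal(empirical_distribution(delta)$probs, c(0, 0, 0, 1))
  expect_error(empirical_distribution(tr, subset = 5), "recorded")
})

test_that("KL divergence matches hand-computed values and is nonnegative", {
  p <- distribution_table(c(0.5, 0.5), 1)
  q <- distribution_table(c(0.75, 0.25), 1)
  expect_equal(kl_divergence(p, p), 0)
  expect_equal(kl_divergence(p, q),
               0.5 * log(0.5 / 0.75) + 0.5 * log(0.5 / 0.25),
               tolerance = 1e-12)
  expect_equal(round(kl_divergence(p, q), 6), 0.143841)
  set.seed(31)
  for (i in 1:20) {
    a <- distribution_table(runif(8), 1:3)
    b <- distribution_table(runif(8) + 0.01, 1:3)
    expect_gte(kl_divergence(a, b), 0)
  }
  # zero reference mass on an observed state is an error
  z <- distribution_table(c(1, 0), 1)
  expect_error(kl_divergence(p, z), "smooth")
  # 0 log 0 = 0 on the empirical side
  expect_equal(kl_divergence(z, q), log(1 / 0.75), tolerance = 1e-12)
  expect_error(kl_divergence(p, distribution_table(c(0.5, 0.5), 2)), "subset")
})

test_that("entropy has the right extremes and bound", {
  m6 <- distribution_table(rep(1, 64), 1:6)
  expect_equal(entropy(m6), 6 * log(2), tolerance = 1e-12)
  expect_equal(entropy(distribution_table(c(0, 1, 0, 0), 1:2)), 0)
  set.seed(32)
  for (i in 1:20) {
    d <- distribution_table(runif(16), 1:4)
    expect_lte(entropy(d), 4 * log(2) + 1e-12)
  }
})

test_that("smoothing gives full support and preserves normalization", {
  d <- distribution_table(c(0.9, 0.1, 0, 0), 1:2)
  s <- smooth_distribution(d, n_samples = 1000)
  expect_true(all(s$probs > 0))
  expect_equal(sum(s$probs), 1, tolerance = 1e-12)
  expect_equal(s$probs[1], 901 / 1004, tolerance = 1e-12)
})

test_that("pairwise unit correlations recover exact Boltzmann correlations", {
  # two-unit machine with strong coupling and compensating negative biases:
  # both the empty and the full state are likely, so the correlation is large
  w <- 6
  net <- sampling_network(matrix(c(0, w, w, 0), 2), c(-3, -3), 1)
  d <- boltzmann_distribution(net)
  p <- d$probs
  m1 <- p[2] + p[4]; m2 <- p[3] + p[4]
  exact <- (p[4] - m1 * m2) / sqrt(m1 * (1 - m1) * m2 * (1 - m2))
  expect_gt(exact, 0.5)
  cfg <- simulation_config(n_samples = 1e5, seed = 33)
  tr <- run_simulation(net, noise_intrinsic(), cfg)
  cm <- pairwise_unit_correlations(tr)
  expect_equal(diag(cm), c(1, 1))
  expect_lt(abs(cm[1, 2] - exact), 0.05)
})

test_that("independent units are uncorrelated within sampling error", {
  net <- sampling_network(matrix(0, 2, 2), c(0, 0), 1)
  cfg <- simulation_config(n_samples = 5e4, seed = 34)
  tr <- run_simulation(net, noise_intrinsic(), cfg)
  cm <- pairwise_unit_correlations(tr)
  expect_lt(abs(cm[1, 2]), 4 / sqrt(5e4))
  frozen <- tr
  frozen$states[, 2] <- 1L
  expect_warning(res <- pairwise_unit_correlations(frozen), "zero-variance")
  expect_true(is.na(res[1, 2]))
})

test_that("empirical input correlation decomposition satisfies its identity", {
  np <- small_noise_params()
  probe <- sampling_network(matrix(0, 10, 10), rep(0, 10), 1)
  for (kind in c("shared", "network")) {
    noise <- build_backend(kind, 10, np, seed = 35)
    cfg <- simulation_config(n_samples = 3e4, T_warmup = 300, seed = 36,
                             record_subset = 1:10, snapshot_every = 3,
                             probe_targets = 1:10, source_cov = TRUE)
    tr <- run_simulation(probe, noise, cfg)
    rep <- input_correlation_empirical(tr, noise$projection, n_pairs = 45)
    expect_equal(rep$pairs$C_in, rep$pairs$C_shared + rep$pairs$C_corr,
                 tolerance = 1e-9)
    expect_gt(rep$C_shared, 0)
    if (kind == "shared") {
      # uncorrelated sources: the correlation term is small noise around zero
      expect_lt(abs(rep$C_corr), 0.2 * rep$C_shared)
      expect_gt(rep$rho_mean, 0)
    } else {
      expect_lt(rep$C_corr, 0)
      expect_lt(abs(rep$C_in), rep$C_shared)
    }
  }
})

test_that("total variation to the exact target shrinks with samples", {
  net <- tiny_net(M = 5, mu_BM = -0.05, seed = 3)
  target <- boltzmann_distribution(net)
  cfg <- simulation_config(n_samples = 1e6, seed = 37)
  tr <- run_simulation(net, noise_intrinsic(), cfg)
  emp <- empirical_distribution(tr)
  tvd <- 0.5 * sum(abs(emp$probs - target$probs))
  expect_lt(tvd, 0.01)
})
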