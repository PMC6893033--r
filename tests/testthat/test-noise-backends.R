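test_that("projections have exact in-degree, sign composition and Dale's law", {
  for (seed in 1:5) {
    p <- build_projection(N = 100, K = 50, gamma = 0.8, w = 0.05, g = 8,
                          n_targets = 15, seed = seed)
    nz <- p$m != 0
    expect_true(all(rowSums(nz) == 50))
    expect_true(all(rowSums(p$m > 0) == round(0.8 * 50)))
    # Dale's law: every source column single-signed
    col_ok <- apply(p$m, 2, function(col) {
      s <- unique(sign(col[col != 0]))
      length(s) <= 1
    })
    expect_true(all(col_ok))
    expect_true(all(p$m %in% c(0, 0.05, -0.4)))
  }
})

test_that("fully connected projections share all sources", {
  p <- build_projection(N = 30, K = 30, gamma = 0.8, w = 0.1, g = 8,
                        n_targets = 4, seed = 2)
  expect_true(all(p$m != 0))
  expect_error(build_projection(N = 10, K = 11, gamma = 0.8, w = 1, g = 1,
                                n_targets = 2, seed = 1), "K")
})

test_that("pairs of targets share about K^2/N sources", {
  p <- build_projection(N = 100, K = 50, gamma = 0.8, w = 0.05, g = 8,
                        n_targets = 30, seed = 3)
  nz <- p$m != 0
  pairs <- utils::combn(30, 2)
  shared <- apply(pairs[, 1:200], 2, function(ij) sum(nz[ij[1], ] & nz[ij[2], ]))
  # exact split expectation: K_E^2/N_E + K_I^2/N_I = 40^2/80 + 10^2/20 = 25
  expect_lt(abs(mean(shared) - 25) / 25, 0.1)
})

test_that("shared pools set their activity through the inverse logistic bias", {
  expect_equal(make_shared_pool(10, mean_activity = 0.5)$biases, rep(0, 10))
  expect_equal(make_shared_pool(5, mean_activity = 1 / (1 + exp(-1)),
                                beta_pool = 1)$biases,
               rep(1, 5), tolerance = 1e-6)
  expect_error(make_shared_pool(5, mean_activity = 1), "mean_activity")
})

test_that("simulated pool activity matches its target and is uncorrelated", {
  N <- 200
  pool <- make_shared_pool(N, mean_activity = 0.35)
  proj <- build_projection(N, 50, 0.8, 0.05, 8, 1, seed = 1)
  cfg <- simulation_config(n_samples = 1e5, T_warmup = 100, seed = 9,
                           record_subset = 1:40, record_noise_updates = TRUE,
                           snapshot_every = 50, source_cov = TRUE)
  tr <- run_simulation(NULL, noise_shared(pool, proj), cfg)
  n_events_per_unit <- 1e5 / N
  se <- sqrt(0.35 * 0.65 / n_events_per_unit) / sqrt(N)
  expect_lt(abs(mean(tr$source_mean) - 0.35), 3 * se)
  # pairwise correlations of snapshot activity vanish on average
  cv <- tr$source_cov
  d <- sqrt(diag(cv))
  cm <- cv / outer(d, d)
  set.seed(1)
  pairs <- replicate(100, sample.int(N, 2))
  rhos <- cm[t(pairs)]
  expect_lt(abs(mean(rhos)), 3 * sd(rhos) / sqrt(100))
})

test_that("noise networks have exact in-degree and inhibition-dominated coupling", {
  nn <- make_noise_network(120, 40, 0.8, 0.05, 8, seed = 4)
  indeg <- table(factor(nn$edges$target, levels = 1:120))
  expect_true(all(indeg == 40))
  expect_true(all(nn$edges$target != nn$edges$source))
  mean_w <- 40 * 0.05 * (0.8 - 0.2 * 8)
  expect_lt(mean_w, 0)
  expect_equal(unique(nn$biases), -mean_w * 0.5)
  expect_warning(make_noise_network(50, 10, 0.8, 0.05, g = 2, seed = 1),
                 "inhibition")
})

test_that("noise-network activity matches the mean-field rate", {
  nn <- make_noise_network(300, 100, 0.8, 0.05, 8, 0.5, seed = 11)
  proj <- build_projection(300, 100, 0.8, 0.05, 8, 1, seed = 2)
  cfg <- simulation_config(n_samples = 5e5, T_warmup = 1000, seed = 5,
                           record_subset = 1:4, record_noise_updates = TRUE,
                           snapshot_every = 100)
  tr <- run_simulation(NULL, noise_network(nn, proj), cfg)
  ps <- selfconsistent_stats(list(N = 300, K = 100, gamma = 0.8, w = 0.05,
                                  g = 8, target_activity = 0.5))
  expect_lt(abs(mean(tr$source_mean) - (0.8 * ps$rate_E + 0.2 * ps$rate_I)),
            0.05)
})

test_that("background input equals the projection row times the source state", {
  M <- 3; N <- 25
  pool <- make_shared_pool(N, 0.8, 0.5, 1)
  proj <- build_projection(N, 10, 0.8, 0.05, 8, M, seed = 4)
  net <- sampling_network(matrix(0, M, M), c(-0.1, 0, 0.1), 1)
  cfg <- simulation_config(n_samples = 500, T_warmup = 10, seed = 6,
                           record_subset = 1:(M + N), snapshot_every = 1,
                           probe_targets = 1:M)
  tr <- run_simulation(net, noise_shared(pool, proj), cfg)
  z <- tr$states[, (M + 1):(M + N)]
  expect_equal(max(abs(z %*% t(proj$m) - tr$probe_fields)), 0,
               tolerance = 1e-12)
})

test_that("dense inhibition-dominated noise networks lock into fixed points", {
  locks <- vapply(1:10, function(sd) {
    nn <- make_noise_network(100, 95, 0.8, 0.05, 8, 0.5, seed = sd)
    proj <- build_projection(100, 95, 0.8, 0.05, 8, 1, seed = sd)
    cfg <- simulation_config(n_samples = 1e4, T_warmup = 0, seed = sd,
                             record_subset = 1:100,
                             record_noise_updates = TRUE)
    tr <- run_simulation(NULL, noise_network(nn, proj), cfg)
    detect_fixed_point(tr, 2000)
  }, logical(1))
  expect_gte(sum(locks), 9)
})

test_that("sparse noise networks remain irregular", {
  nn <- make_noise_network(200, 100, 0.8, 0.05, 8, 0.5, seed = 3)
  proj <- build_projection(200, 100, 0.8, 0.05, 8, 1, seed = 3)
  cfg <- simulation_config(n_samples = 1e5, T_warmup = 0, seed = 3,
                           record_subset = 1:200, record_noise_updates = TRUE)
  tr <- run_simulation(NULL, noise_network(nn, proj), cfg)
  expect_false(detect_fixed_point(tr, 5000))
  flips <- colSums(abs(diff(tr$states)))
  expect_true(all(flips > 0))
})

test_that("detect_fixed_point handles trivial traces and bad input", {
  const_tr <- structure(list(states = matrix(1L, 50, 3), times = 1:50),
                        class = "state_trace")
  expect_true(detect_fixed_point(const_tr, 50))
  changing <- const_tr
  changing$states[49, 2] <- 0L
  expect_false(detect_fixed_point(changing, 10))
  empty <- structure(list(states = matrix(0L, 0, 2), times = numeric(0)),
                     class = "state_trace")
  expect_error(detect_fixed_point(empty, 1), "empty")
  expect_error(detect_fixed_point(const_tr, 100), "window")
})
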