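test_that("noise-strength relations evaluate to their closed forms", {
  expect_equal(sigma_from_beta(1, "integral"), log(2) * sqrt(2 * pi),
               tolerance = 1e-12)
  expect_equal(sigma_from_beta(1, "taylor"), 2 * sqrt(2) / sqrt(pi),
               tolerance = 1e-12)
  # 1/beta scaling for both methods
  for (m in c("integral", "taylor")) {
    expect_equal(sigma_from_beta(2, m), sigma_from_beta(1, m) / 2,
                 tolerance = 1e-12)
  }
  expect_error(sigma_from_beta(0), "beta")
})

test_that("beta_eff inverts the integral matching and is monotone", {
  expect_equal(beta_eff_from_sigma(log(2) * sqrt(2 * pi)), 1, tolerance = 1e-12)
  for (bt in c(0.3, 1, 2.7)) {
    expect_equal(beta_eff_from_sigma(sigma_from_beta(bt, "integral")), bt,
                 tolerance = 1e-12)
  }
  expect_equal(beta_eff_from_sigma(sqrt(1.7)), log(2) * sqrt(2 * pi) / sqrt(1.7),
               tolerance = 1e-6)
  s <- seq(0.1, 5, by = 0.1)
  expect_true(all(diff(beta_eff_from_sigma(s)) < 0))
})

test_that("integral matching condition holds by quadrature", {
  for (bt in c(0.5, 1, 2)) {
    sg <- sigma_from_beta(bt, "integral")
    q <- stats::integrate(function(h) {
      activation_probability("gaussian_erfc", h, mu = 0, sigma = sg)
    }, -Inf, 0, rel.tol = 1e-12)
    expect_lt(abs(q$value - log(2) / bt), 1e-8)
  }
})

test_that("shared-pool input statistics follow the homogeneous closed form", {
  st <- input_stats_shared(list(K = 200, w = 0.05, gamma = 0.8, g = 8,
                                mean_activity = 0.5))
  expect_equal(st$mu, -4, tolerance = 1e-12)
  expect_equal(st$sigma2, 1.7, tolerance = 1e-12)
  # balanced weights: zero mean input for any K, w, z
  st0 <- input_stats_shared(list(K = 77, w = 0.3, gamma = 0.5, g = 1,
                                 mean_activity = 0.21))
  expect_equal(st0$mu, 0, tolerance = 1e-12)
})

test_that("heterogeneous input statistics sum realized projection rows", {
  pool <- make_shared_pool(60, 0.8, 0.4)
  proj <- build_projection(60, 20, 0.8, 0.05, 8, 5, seed = 2)
  backend <- noise_shared(pool, proj)
  st <- input_stats_shared(backend, mode = "heterogeneous")
  expect_equal(st$mu, rowSums(proj$m) * 0.4, tolerance = 1e-12)
  expect_equal(st$sigma2, rowSums(proj$m^2) * 0.4 * 0.6, tolerance = 1e-12)
  # exact split makes every row equal to the homogeneous value
  hom <- input_stats_shared(backend)
  expect_equal(unique(round(st$mu, 10)), round(hom$mu, 10))
})

test_that("empirical pool input moments match the closed form", {
  np <- small_noise_params(mean_activity = 0.5)
  noise <- build_backend("shared", 5, np, seed = 3)
  probe <- sampling_network(matrix(0, 5, 5), rep(0, 5), 1)
  cfg <- simulation_config(n_samples = 5e4, T_warmup = 200, seed = 4,
                           record_subset = 1:5, snapshot_every = 5,
                           probe_targets = 1:5)
  tr <- run_simulation(probe, noise, cfg)
  st <- input_stats_shared(noise)
  emp <- input_stats_empirical(tr$probe_fields[, 1])
  n <- nrow(tr$probe_fields)
  se_mu <- sqrt(st$sigma2 / n) * 3 # snapshots are correlated; allow slack
  expect_lt(abs(emp$mu - st$mu), 3 * se_mu)
  expect_lt(abs(emp$sigma2 - st$sigma2) / st$sigma2, 0.15)
})

test_that("network input statistics add the covariance cross-term", {
  proj <- build_projection(300, 100, 0.8, 0.05, 8, 10, seed = 5)
  base <- population_stats(0.5, 0.5, -2, -2, 0.8, 0.8, 0, 0, 0, b_E = 2, b_I = 2)
  st0 <- input_stats_network(proj, base)
  sh <- input_stats_shared(list(K = 100, w = 0.05, gamma = 0.8, g = 8,
                                mean_activity = 0.5))
  expect_equal(st0$mu, sh$mu, tolerance = 1e-9)
  expect_equal(st0$sigma2, sh$sigma2, tolerance = 1e-9)
  pos <- population_stats(0.5, 0.5, -2, -2, 0.8, 0.8, 0.002, 0, 0,
                          b_E = 2, b_I = 2)
  expect_gt(input_stats_network(proj, pos)$sigma2, st0$sigma2)
  na_stats <- population_stats(0.5, 0.5, -2, -2, 0.8, 0.8)
  expect_error(input_stats_network(proj, na_stats), "missing")
})

test_that("predicted noise-network input variance matches simulation", {
  np <- noise_params(K = 100L, N = 300L)
  noise <- build_backend("network", 10, np, seed = 6)
  ps <- selfconsistent_stats(list(N = 300, K = 100, gamma = 0.8, w = 0.05,
                                  g = 8, target_activity = 0.5))
  pred <- input_stats_network(noise$projection, ps)
  probe <- sampling_network(matrix(0, 10, 10), rep(0, 10), 1)
  cfg <- simulation_config(n_samples = 1e5, T_warmup = 500, seed = 7,
                           record_subset = 1:10, snapshot_every = 10,
                           probe_targets = 1:10)
  tr <- run_simulation(probe, noise, cfg)
  emp_var <- mean(apply(tr$probe_fields, 2, var))
  expect_lt(abs(emp_var - pred$sigma2) / pred$sigma2, 0.15)
  emp_mu <- mean(colMeans(tr$probe_fields))
  expect_lt(abs(emp_mu - pred$mu), 0.1)
})

test_that("empirical input statistics recover known moments", {
  expect_equal(input_stats_empirical(rep(2.5, 1500)),
               input_stats(2.5, 0))
  set.seed(8)
  x <- rnorm(1e5, -4, sqrt(1.7))
  st <- input_stats_empirical(x)
  expect_lt(abs(st$mu - (-4)), 3 * sqrt(1.7 / 1e5))
  expect_lt(abs(st$sigma2 - 1.7), 3 * 1.7 * sqrt(2 / 1e5))
  expect_error(input_stats_empirical(rnorm(100)), "1000")
})

test_that("rescaling preserves the target Boltzmann distribution", {
  net <- tiny_net(M = 5, seed = 17, beta = 1.4)
  expect_equal(rescale_network(net, net$beta, net$beta, 0)$W, net$W)
  beta_eff <- 2.2; mu <- -3.1
  scaled <- rescale_network(net, net$beta, beta_eff, mu)
  expect_equal(scaled$beta, 1)
  # evaluating the rescaled net at beta_eff with the bias shift undone
  # reproduces the original distribution
  back <- sampling_network(scaled$W, scaled$b + mu, beta_eff)
  expect_equal(boltzmann_distribution(back)$probs,
               boltzmann_distribution(net)$probs, tolerance = 1e-12)
  expect_error(rescale_network(net, 1, 0, 0), "beta_eff")
})

test_that("calibrated private noise samples the target distribution", {
  net <- tiny_net(M = 5, mu_BM = -0.05, seed = 3)
  target <- boltzmann_distribution(net)
  noise <- noise_private(0.8, sigma_from_beta(1, "integral"))
  simnet <- calibrated_network(net, noise)
  cfg <- simulation_config(n_samples = 2e5, seed = 19)
  tr <- run_simulation(simnet, noise, cfg)
  expect_lt(kl_divergence(empirical_distribution(tr), target), 0.01)
})

test_that("a calibrated shared pool reproduces the logistic activation", {
  np <- noise_params() # K = 200, sigma^2 = 1.7
  noise <- build_backend("shared", 1, np, seed = 23)
  cal <- calibrate_backend(noise, beta_target = 1)
  hs <- seq(-2, 2, by = 0.5)
  emp <- vapply(hs, function(h) {
    # one Heaviside unit whose rescaled bias realizes field h at beta_eff
    unit <- sampling_network(matrix(0, 1, 1), h / cal$beta_eff - cal$stats$mu, 1)
    cfg <- simulation_config(n_samples = 2e4, T_warmup = 200,
                             seed = round(300 + 10 * h), record_subset = 1)
    mean(run_simulation(unit, noise, cfg)$states[, 1])
  }, numeric(1))
  expect_lt(max(abs(emp - activation_probability("logistic", hs, beta = 1))),
            0.03)
})

test_that("calibration results summarise consistently", {
  noise <- noise_private(0, sqrt(1.7))
  cal <- calibrate_backend(noise, beta_target = 2)
  expect_equal(cal$beta_eff, beta_eff_from_sigma(sqrt(1.7)))
  expect_equal(cal$alpha, 2 / cal$beta_eff)
  g <- glance(cal)
  expect_equal(g$sigma2, 1.7)
  expect_identical(g$kind, "private")
})
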