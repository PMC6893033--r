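default_mf_config <- list(N = 300, K = 100, gamma = 0.8, w = 0.05, g = 8,
                          target_activity = 0.5)

test_that("bias cancellation gives half-activity rates", {
  st <- solve_rates(default_mf_config)
  expect_equal(st$rate_E, 0.5, tolerance = 1e-9)
  expect_equal(st$rate_I, 0.5, tolerance = 1e-9)
  expect_equal(st$a_E, 0.25, tolerance = 1e-9)
  # converged rates satisfy the self-consistency equation
  lhs <- st$rate_E
  rhs <- pnorm((st$mu_E + st$b_E) / st$sigma_E)
  expect_equal(lhs, rhs, tolerance = 1e-8)
})

test_that("rates away from the symmetric point converge self-consistently", {
  cfg <- utils::modifyList(default_mf_config, list(target_activity = 0.3))
  st <- solve_rates(cfg)
  for (al in c("E", "I")) {
    r <- if (al == "E") st$rate_E else st$rate_I
    mu <- if (al == "E") st$mu_E else st$mu_I
    sg <- if (al == "E") st$sigma_E else st$sigma_I
    expect_equal(r, pnorm((mu + st$b_E) / sg), tolerance = 1e-8)
  }
  expect_true(st$rate_E > 0 && st$rate_E < 1)
})

test_that("susceptibility is positive and effective weights inherit signs", {
  for (mu in c(-2, 0, 3)) {
    for (sg in c(0.5, 2)) {
      expect_gt(susceptibility(mu, sg, b = 1), 0)
    }
  }
  # printed variant differs but stays positive
  expect_gt(susceptibility(-2, 0.5, 2, form = "printed"), 0)
  st <- solve_rates(default_mf_config)
  cc <- solve_covariances(default_mf_config, st)
  # E sources excite, so c_EE source terms push positive; I->I term negative
  expect_true(is.finite(cc["c_EE"]) && is.finite(cc["c_II"]))
})

test_that("decoupled covariance system returns zeros", {
  # susceptibility effectively zero when the working point is far below
  # threshold: all effective weights vanish, so all covariances vanish
  far <- population_stats(0.5, 0.5, -50, -50, 1, 1, b_E = 0, b_I = 0)
  cc <- solve_covariances(default_mf_config, far)
  expect_equal(unname(cc), c(0, 0, 0), tolerance = 1e-200)
})

test_that("single-population limit reproduces the scalar covariance formula", {
  # gamma and K chosen so the excitatory in-degree is zero: the inhibitory
  # population decouples and c_II = w~ a / (N_I (1 - w~)) must hold.
  cfg <- list(N = 101, K = 1, gamma = 0.001, w = 0.25, g = 8,
              target_activity = 0.5)
  # craft moments with susceptibility exactly 1: sigma = 1/sqrt(2*pi), mu+b=0
  sg <- 1 / sqrt(2 * pi)
  st <- population_stats(0.5, 0.5, 0, 0, sg, sg, b_E = 0, b_I = 0)
  cc <- solve_covariances(cfg, st)
  # w~_II = S * K_I * (-g w) = 1 * 1 * -2; scalar solution -2*0.25/(100*3)
  expect_equal(unname(cc["c_II"]), -1 / 600, tolerance = 1e-12)
})

test_that("self-consistent scheme converges and matches its definition", {
  ps <- selfconsistent_stats(default_mf_config)
  # first outer iteration: rates at zero correlations, then covariances
  st1 <- solve_rates(default_mf_config, covariances = c(0, 0, 0))
  cc1 <- solve_covariances(default_mf_config, st1)
  st2 <- solve_rates(default_mf_config, covariances = cc1)
  expect_equal(ps$rate_E, st2$rate_E, tolerance = 1e-4)
  # converged values satisfy both fixed-point equations
  stc <- solve_rates(default_mf_config,
                     covariances = c(ps$c_EE, ps$c_EI, ps$c_II))
  expect_equal(stc$rate_E, ps$rate_E, tolerance = 1e-7)
  ccc <- solve_covariances(default_mf_config, stc)
  expect_equal(unname(ccc), c(ps$c_EE, ps$c_EI, ps$c_II), tolerance = 1e-7)
})

test_that("mean-field covariances agree with simulation in sign and scale", {
  nn <- make_noise_network(300, 100, 0.8, 0.05, 8, 0.5, seed = 11)
  proj <- build_projection(300, 100, 0.8, 0.05, 8, 1, seed = 2)
  cfg <- simulation_config(n_samples = 1.5e6, T_warmup = 2000, seed = 5,
                           record_subset = 1, record_noise_updates = TRUE,
                           snapshot_every = 300, source_cov = TRUE)
  tr <- run_simulation(NULL, noise_network(nn, proj), cfg)
  nE <- 240
  cv <- tr$source_cov
  off <- function(m) m[upper.tri(m)]
  sim <- c(mean(off(cv[1:nE, 1:nE])),
           mean(cv[1:nE, (nE + 1):300]),
           mean(off(cv[(nE + 1):300, (nE + 1):300])))
  ps <- selfconsistent_stats(default_mf_config)
  mf <- c(ps$c_EE, ps$c_EI, ps$c_II)
  expect_equal(sign(sim), sign(mf))
  expect_true(all(abs(sim - mf) / abs(mf) < 0.5))
})

test_that("input-correlation decomposition behaves as expected", {
  proj_pars <- list(K = 200, N = 222, gamma = 0.8, w = 0.05, g = 8)
  un <- predict_input_correlations(proj_pars, pool_population_stats(0.5))
  expect_equal(un$C_corr, 0)
  expect_gt(un$C_shared, 0)
  expect_equal(un$C_in, un$C_shared + un$C_corr)

  ps <- selfconsistent_stats(utils::modifyList(proj_pars,
                                               list(target_activity = 0.5)))
  corr <- predict_input_correlations(proj_pars, ps)
  expect_lt(corr$C_corr, 0)
  expect_equal(corr$C_in, corr$C_shared + corr$C_corr, tolerance = 1e-12)
  expect_lt(abs(corr$C_in), corr$C_shared)
})

test_that("predicted shared-pool correlation decays as 1/N at fixed K", {
  K <- 200
  Ns <- K * c(1, 2, 4, 8, 16)
  rhos <- vapply(Ns, function(N) {
    predict_input_correlations(list(K = K, N = N, gamma = 0.8, w = 0.05,
                                    g = 8), pool_population_stats(0.5))$rho
  }, numeric(1))
  slope <- coef(lm(log(rhos) ~ log(Ns)))[2]
  expect_lt(abs(slope - (-1)), 0.15)
})

test_that("network C_in is suppressed for inhibition-dominated parameters", {
  for (pars in list(list(K = 100, N = 300, gamma = 0.8, w = 0.05, g = 8),
                    list(K = 200, N = 400, gamma = 0.8, w = 0.05, g = 6),
                    list(K = 50, N = 200, gamma = 0.75, w = 0.1, g = 8))) {
    ps <- selfconsistent_stats(utils::modifyList(pars,
                                                 list(target_activity = 0.5)))
    pr <- predict_input_correlations(pars, ps)
    expect_lt(abs(pr$C_in), pr$C_shared)
    expect_lt(pr$C_corr, 0)
  }
})

test_that("non-convergence is reported", {
  expect_error(selfconsistent_stats(default_mf_config, tol = 0), "tol")
  asym <- utils::modifyList(default_mf_config, list(target_activity = 0.3))
  expect_error(solve_rates(asym, max_iter = 2L), "converge")
})
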