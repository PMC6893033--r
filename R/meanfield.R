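#' Population statistics of a noise network
#'
#' Container for the two-population (excitatory/inhibitory) mean-field
#' description of a recurrent noise network: rates, input moments,
#' single-unit activity variances `a = r * (1 - r)` and population-averaged
#' pairwise covariances.
#'
#' @param rate_E,rate_I population rates in (0, 1).
#' @param mu_E,mu_I mean recurrent input per population (bias excluded).
#' @param sigma_E,sigma_I input standard deviations.
#' @param c_EE,c_EI,c_II population-averaged pairwise covariances
#'   (`c_EI` is used symmetrically).
#' @param b_E,b_I population biases.
#' @return An object of class `population_stats`.
#' @export
population_stats <- function(rate_E, rate_I, mu_E, mu_I, sigma_E, sigma_I,
                             c_EE = NA_real_, c_EI = NA_real_, c_II = NA_real_,
                             b_E = 0, b_I = 0) {
  if (rate_E <= 0 || rate_E >= 1 || rate_I <= 0 || rate_I >= 1) {
    stop("rates must lie in (0, 1)")
  }
  structure(list(rate_E = rate_E, rate_I = rate_I, mu_E = mu_E, mu_I = mu_I,
                 sigma_E = sigma_E, sigma_I = sigma_I,
                 a_E = rate_E * (1 - rate_E), a_I = rate_I * (1 - rate_I),
                 c_EE = c_EE, c_EI = c_EI, c_II = c_II, b_E = b_E, b_I = b_I),
            class = "population_stats")
}

#' @export
print.population_stats <- function(x, ...) {
  cat(sprintf("<population_stats> rate_E = %.4f, rate_I = %.4f\n", x$rate_E, x$rate_I))
  cat(sprintf("  mu = (%.4g, %.4g), sigma = (%.4g, %.4g)\n",
              x$mu_E, x$mu_I, x$sigma_E, x$sigma_I))
  cat(sprintf("  c_EE = %.4g, c_EI = %.4g, c_II = %.4g\n", x$c_EE, x$c_EI, x$c_II))
  invisible(x)
}

#' @rdname population_stats
#' @param x a `population_stats`.
#' @param ... unused.
#' @export
glance.population_stats <- function(x, ...) {
  tibble::tibble(rate_E = x$rate_E, rate_I = x$rate_I, mu_E = x$mu_E,
                 mu_I = x$mu_I, sigma_E = x$sigma_E, sigma_I = x$sigma_I,
                 c_EE = x$c_EE, c_EI = x$c_EI, c_II = x$c_II)
}

# Population-level connectivity parameters of a noise network. By default the
# fixed-in-degree reading K_aE = round(gamma K), K_aI = K - round(gamma K) is
# used; `indegree_rule = "printed"` restores the density-based reading
# K_aE = gamma N, K_aI = (1 - gamma) N.
mf_params <- function(config, indegree_rule = c("fixed", "printed")) {
  indegree_rule <- match.arg(indegree_rule)
  p <- if (inherits(config, "noise_net")) config else as.list(config)
  N <- p$N; K <- p$K; gamma <- p$gamma; w <- p$w; g <- p$g
  target <- if (!is.null(p$target_activity)) p$target_activity else 0.5
  N_E <- ceiling(gamma * N); N_I <- N - N_E
  if (indegree_rule == "fixed") {
    K_E <- round(gamma * K); K_I <- K - K_E
  } else {
    K_E <- gamma * N; K_I <- (1 - gamma) * N
  }
  b <- -(K_E * w - K_I * g * w) * target
  list(N_E = N_E, N_I = N_I, K_E = K_E, K_I = K_I, w_E = w, w_I = -g * w,
       b = b, target = target)
}

#' Linear-response susceptibility of a Heaviside unit
#'
#' Slope of the unit's mean activation `erfc(-(mu + b)/(sqrt(2) sigma))/2`
#' with respect to its mean input: the Gaussian density of the input
#' fluctuations at threshold,
#' `S = exp(-(mu + b)^2 / (2 sigma^2)) / (sqrt(2 pi) sigma)`. The variant
#' `form = "printed"` uses `2 sigma` instead of `2 sigma^2` in the exponent
#' (dimensionally inconsistent; retained for comparison only).
#'
#' @param mu mean input (bias excluded).
#' @param sigma input standard deviation.
#' @param b bias.
#' @param form `"density"` (default) or `"printed"`.
#' @return The susceptibility (always positive).
#' @export
susceptibility <- function(mu, sigma, b = 0, form = c("density", "printed")) {
  form <- match.arg(form)
  denom <- if (form == "density") 2 * sigma^2 else 2 * sigma
  exp(-(mu + b)^2 / denom) / (sqrt(2 * pi) * sigma)
}

#' Self-consistent population rates of a noise network
#'
#' Damped fixed-point iteration of the two-population self-consistency
#' `r_a = erfc(-(mu_a + b_a) / (sqrt(2) sigma_a)) / 2` with
#' `mu_a = sum_b K_ab w_ab r_b` and
#' `sigma_a^2 = sum_b K_ab w_ab^2 a_b + sum_bc (Kw)_ab (Kw)_ac c_bc`.
#'
#' @param config a [make_noise_network()] or a list with `N`, `K`, `gamma`,
#'   `w`, `g`, `target_activity`.
#' @param covariances numeric `(c_EE, c_EI, c_II)`; zeros for the
#'   uncorrelated approximation.
#' @param tol convergence tolerance on the rates.
#' @param max_iter iteration cap; non-convergence is an error reporting the
#'   residual.
#' @param damping damping factor on the rate update (fraction of the new
#'   value used).
#' @param indegree_rule `"fixed"` (default) or `"printed"`, see
#'   [selfconsistent_stats()].
#' @return A [population_stats()] with the supplied covariances attached.
#' @export
solve_rates <- function(config, covariances = c(0, 0, 0), tol = 1e-10,
                        max_iter = 10000L, damping = 0.5,
                        indegree_rule = c("fixed", "printed")) {
  p <- mf_params(config, match.arg(indegree_rule))
  cEE <- covariances[1]; cEI <- covariances[2]; cII <- covariances[3]
  r <- c(E = 0.5, I = 0.5)
  Kw <- c(E = p$K_E * p$w_E, I = p$K_I * p$w_I)
  cov_term <- Kw["E"]^2 * cEE + 2 * Kw["E"] * Kw["I"] * cEI + Kw["I"]^2 * cII
  mu <- sig <- c(E = NA_real_, I = NA_real_)
  for (it in seq_len(max_iter)) {
    a <- r * (1 - r)
    mu[] <- p$K_E * p$w_E * r["E"] + p$K_I * p$w_I * r["I"]
    s2 <- p$K_E * p$w_E^2 * a["E"] + p$K_I * p$w_I^2 * a["I"] + cov_term
    if (any(s2 <= 0)) stop("non-positive input variance in rate iteration")
    sig[] <- sqrt(s2)
    r_new <- stats::pnorm((mu + p$b) / sig)
    delta <- max(abs(r_new - r))
    r <- (1 - damping) * r + damping * r_new
    if (delta < tol) {
      return(population_stats(r[["E"]], r[["I"]], mu[["E"]], mu[["I"]],
                              sig[["E"]], sig[["I"]], cEE, cEI, cII,
                              b_E = p$b, b_I = p$b))
    }
  }
  stop(sprintf("rate iteration did not converge: residual %.3g after %d iterations",
               max(abs(r)), max_iter))
}

#' Population-averaged covariances of a noise network
#'
#' Builds the effective linearized weights
#' `w~_ab = S(mu_a, sigma_a) * K_ab * w_ab` and solves the linear system
#' `2 c_ab = sum_c (w~_ac c_cb + w~_bc c_ca) + w~_ab a_b / N_b + w~_ba a_a / N_a`
#' exactly for `(c_EE, c_EI, c_II)`.
#'
#' @inheritParams solve_rates
#' @param stats a converged [population_stats()] (rates and moments).
#' @param susceptibility_form passed to [susceptibility()].
#' @return Named numeric vector `(c_EE, c_EI, c_II)`.
#' @export
solve_covariances <- function(config, stats,
                              susceptibility_form = c("density", "printed"),
                              indegree_rule = c("fixed", "printed")) {
  p <- mf_params(config, match.arg(indegree_rule))
  sform <- match.arg(susceptibility_form)
  S_E <- susceptibility(stats$mu_E, stats$sigma_E, stats$b_E, sform)
  S_I <- susceptibility(stats$mu_I, stats$sigma_I, stats$b_I, sform)
  wt <- matrix(c(S_E * p$K_E * p$w_E, S_E * p$K_I * p$w_I,
                 S_I * p$K_E * p$w_E, S_I * p$K_I * p$w_I),
               2, 2, byrow = TRUE,
               dimnames = list(c("E", "I"), c("E", "I")))
  a <- c(E = stats$a_E, I = stats$a_I)
  Np <- c(E = p$N_E, I = p$N_I)
  # unknowns x = (c_EE, c_EI, c_II)
  A <- matrix(0, 3, 3)
  rhs <- numeric(3)
  pairs <- list(c("E", "E"), c("E", "I"), c("I", "I"))
  idx <- function(a1, b1) {
    key <- paste(sort(c(a1, b1)), collapse = "")
    match(key, c("EE", "EI", "II"))
  }
  for (r in 1:3) {
    al <- pairs[[r]][1]; be <- pairs[[r]][2]
    row <- numeric(3)
    row[idx(al, be)] <- row[idx(al, be)] + 2
    for (ga in c("E", "I")) {
      row[idx(ga, be)] <- row[idx(ga, be)] - wt[al, ga]
      row[idx(ga, al)] <- row[idx(ga, al)] - wt[be, ga]
    }
    A[r, ] <- row
    rhs[r] <- wt[al, be] * a[be] / Np[be] + wt[be, al] * a[al] / Np[al]
  }
  if (abs(det(A)) < 1e-14) stop("singular covariance system")
  x <- solve(A, rhs)
  c(c_EE = x[1], c_EI = x[2], c_II = x[3])
}

#' Self-consistent rates and covariances of a noise network
#'
#' Alternates [solve_rates()] (with the current covariances) and
#' [solve_covariances()] (with the current rates) until successive rates and
#' covariances change by less than `tol`. The first iteration solves the
#' rates under zero correlations.
#'
#' @inheritParams solve_rates
#' @inheritParams solve_covariances
#' @param tol joint convergence tolerance.
#' @param max_iter outer-iteration cap.
#' @return A converged [population_stats()].
#' @export
selfconsistent_stats <- function(config, tol = 1e-8, max_iter = 200L,
                                 susceptibility_form = c("density", "printed"),
                                 indegree_rule = c("fixed", "printed")) {
  if (tol <= 0) stop("tol must be positive")
  sform <- match.arg(susceptibility_form)
  irule <- match.arg(indegree_rule)
  cc <- c(0, 0, 0)
  prev <- NULL
  for (it in seq_len(max_iter)) {
    st <- solve_rates(config, covariances = cc, indegree_rule = irule)
    cc_new <- solve_covariances(config, st, susceptibility_form = sform,
                                indegree_rule = irule)
    if (!is.null(prev)) {
      d <- max(abs(c(st$rate_E - prev$rate_E, st$rate_I - prev$rate_I,
                     cc_new - cc)))
      if (d < tol) {
        return(population_stats(st$rate_E, st$rate_I, st$mu_E, st$mu_I,
                                st$sigma_E, st$sigma_I, cc_new[[1]],
                                cc_new[[2]], cc_new[[3]], st$b_E, st$b_I))
      }
    }
    prev <- st
    cc <- cc_new
  }
  stop("self-consistent iteration did not converge")
}

#' Predicted input-correlation decomposition for sampling units
#'
#' Expected covariance between the background inputs of two sampling units
#' drawing from the same source population, split into the shared-source
#' term and the source-correlation term:
#' `C_shared = (K_E^2 / N_E) w^2 a_E + (K_I^2 / N_I) (g w)^2 a_I`,
#' `C_corr = (K_E w)^2 c_EE - 2 K_E K_I g w^2 c_EI + (K_I g w)^2 c_II`,
#' `C_in = C_shared + C_corr`. For an uncorrelated shared pool the
#' covariances are zero and `C_corr = 0`. Also returns the predicted input
#' correlation coefficient `rho = C_in / sigma2` with `sigma2` the per-unit
#' input variance under the same statistics.
#'
#' @param proj a [build_projection()] or a list with `K`, `gamma`, `w`, `g`,
#'   `N`.
#' @param stats a [population_stats()]; for a shared pool use
#'   [pool_population_stats()].
#' @return A one-row tibble with `C_shared`, `C_corr`, `C_in`, `sigma2`,
#'   `rho`.
#' @export
predict_input_correlations <- function(proj, stats) {
  p <- if (inherits(proj, "projection_matrix")) proj else as.list(proj)
  K <- p$K; gamma <- p$gamma; w <- p$w; g <- p$g; N <- p$N
  N_E <- ceiling(gamma * N); N_I <- N - N_E
  K_E <- round(gamma * K); K_I <- K - K_E
  cEE <- if (is.na(stats$c_EE)) 0 else stats$c_EE
  cEI <- if (is.na(stats$c_EI)) 0 else stats$c_EI
  cII <- if (is.na(stats$c_II)) 0 else stats$c_II
  C_shared <- (K_E^2 / N_E) * w^2 * stats$a_E + (K_I^2 / N_I) * (g * w)^2 * stats$a_I
  C_corr <- (K_E * w)^2 * cEE - 2 * K_E * K_I * g * w^2 * cEI + (K_I * g * w)^2 * cII
  sigma2 <- K_E * w^2 * stats$a_E + K_I * (g * w)^2 * stats$a_I +
    K_E * (K_E - 1) * w^2 * cEE - 2 * K_E * K_I * g * w^2 * cEI +
    K_I * (K_I - 1) * (g * w)^2 * cII
  tibble::tibble(C_shared = C_shared, C_corr = C_corr,
                 C_in = C_shared + C_corr, sigma2 = sigma2,
                 rho = (C_shared + C_corr) / sigma2)
}

#' Population statistics of an uncorrelated shared pool
#'
#' Degenerate [population_stats()] for a pool of independent sources with
#' identical mean activity: both population rates equal `mean_activity` and
#' all pairwise covariances are zero.
#'
#' @param pool a [make_shared_pool()] or a mean activity in (0, 1).
#' @return A [population_stats()].
#' @export
pool_population_stats <- function(pool) {
  z <- if (inherits(pool, "shared_pool")) pool$mean_activity else pool
  population_stats(z, z, 0, 0, 1, 1, 0, 0, 0)
}
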