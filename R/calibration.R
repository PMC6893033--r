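#' Noise strength for a target inverse temperature
#'
#' Relates the standard deviation `sigma` of additive Gaussian noise on a
#' Heaviside unit to the inverse temperature `beta` of the logistic
#' activation it is meant to emulate. `method = "taylor"` equates the linear
#' Taylor coefficients of the two activation functions at `h = 0`:
#' `sigma = 2 * sqrt(2) / (sqrt(pi) * beta)`. `method = "integral"` (the
#' better fit, and the package default throughout) matches the integrals of
#' the activation functions over `(-Inf, 0]`:
#' `sigma = log(2) * sqrt(2 * pi) / beta`.
#'
#' @param beta positive inverse temperature.
#' @param method `"integral"` (default) or `"taylor"`.
#' @return The noise standard deviation.
#' @export
sigma_from_beta <- function(beta, method = c("integral", "taylor")) {
  method <- match.arg(method)
  if (any(beta <= 0)) stop("beta must be positive")
  if (method == "taylor") 2 * sqrt(2) / (sqrt(pi) * beta)
  else log(2) * sqrt(2 * pi) / beta
}

#' Effective inverse temperature of a Gaussian-noise unit
#'
#' Inverts the integral-matching relation: `beta_eff = log(2) * sqrt(2*pi) /
#' sigma`. Strictly decreasing in `sigma`.
#'
#' @param sigma positive noise standard deviation.
#' @return The effective inverse temperature.
#' @export
beta_eff_from_sigma <- function(sigma) {
  if (any(sigma <= 0)) stop("sigma must be positive")
  log(2) * sqrt(2 * pi) / sigma
}

#' Input statistics
#'
#' Mean and variance of the background input delivered to sampling units.
#' @param mu mean background input (scalar or per-unit vector).
#' @param sigma2 nonnegative background-input variance (same shape as `mu`).
#' @return An object of class `input_stats`.
#' @export
input_stats <- function(mu, sigma2) {
  if (any(sigma2 < 0)) stop("sigma2 must be nonnegative")
  structure(list(mu = mu, sigma2 = sigma2), class = "input_stats")
}

#' @export
print.input_stats <- function(x, ...) {
  cat(sprintf("<input_stats> mu = %s, sigma2 = %s\n",
              paste(signif(x$mu, 6), collapse = ", "),
              paste(signif(x$sigma2, 6), collapse = ", ")))
  invisible(x)
}

#' Input statistics for a shared pool of uncorrelated sources
#'
#' Homogeneous mode uses the closed forms
#' `mu = K * w * (gamma - (1 - gamma) * g) * z` and
#' `sigma2 = K * w^2 * (gamma + (1 - gamma) * g^2) * z * (1 - z)` with
#' `z` the pool's mean activity. Heterogeneous mode evaluates the per-target
#' sums `mu_i = sum_k m_ik * z` and `sigma2_i = sum_k m_ik^2 * z * (1 - z)`
#' over the realized projection rows.
#'
#' @param x a [noise_shared()] backend, or a list with elements
#'   `K`, `w`, `gamma`, `g`, `mean_activity`.
#' @param mode `"homogeneous"` (one global pair) or `"heterogeneous"`
#'   (per-target vectors; requires a backend with a realized projection).
#' @return An [input_stats()].
#' @export
input_stats_shared <- function(x, mode = c("homogeneous", "heterogeneous")) {
  mode <- match.arg(mode)
  if (inherits(x, "noise_shared")) {
    z <- x$pool$mean_activity
    if (mode == "heterogeneous") {
      m <- x$projection$m
      return(input_stats(rowSums(m) * z, rowSums(m^2) * z * (1 - z)))
    }
    p <- x$projection
    K <- p$K; w <- p$w; gamma <- p$gamma; g <- p$g
  } else {
    if (mode == "heterogeneous") stop("heterogeneous mode needs a realized projection")
    K <- x$K; w <- x$w; gamma <- x$gamma; g <- x$g; z <- x$mean_activity
  }
  input_stats(K * w * (gamma - (1 - gamma) * g) * z,
              K * w^2 * (gamma + (1 - gamma) * g^2) * z * (1 - z))
}

#' Input statistics for a recurrent noise network
#'
#' Extends the shared-pool variance by the cross-term
#' `sum_{k != l} m_ik * m_il * c_kl` arising from pairwise correlations
#' between noise units, evaluated with the population-averaged covariances
#' `c_EE`, `c_EI`, `c_II` from [selfconsistent_stats()] and the realized
#' excitatory/inhibitory in-degree counts of each projection row.
#'
#' @param proj a [build_projection()] onto the sampling units.
#' @param popstats a [population_stats] (mean-field or empirical).
#' @param mode `"homogeneous"` (average over rows) or `"heterogeneous"`.
#' @return An [input_stats()].
#' @export
input_stats_network <- function(proj, popstats,
                                mode = c("homogeneous", "heterogeneous")) {
  mode <- match.arg(mode)
  stopifnot(inherits(proj, "projection_matrix"),
            inherits(popstats, "population_stats"))
  if (any(is.na(c(popstats$c_EE, popstats$c_EI, popstats$c_II)))) {
    stop("population covariances are missing")
  }
  m <- proj$m
  exc_cols <- seq_len(proj$n_exc)
  w <- proj$w; g <- proj$g
  rE <- popstats$rate_E; rI <- popstats$rate_I
  aE <- popstats$a_E; aI <- popstats$a_I
  KE <- rowSums(m[, exc_cols, drop = FALSE] != 0)
  KI <- rowSums(m[, -exc_cols, drop = FALSE] != 0)
  mu <- KE * w * rE - KI * g * w * rI
  var_uncorr <- KE * w^2 * aE + KI * g^2 * w^2 * aI
  cross <- KE * (KE - 1) * w^2 * popstats$c_EE -
    2 * KE * KI * g * w^2 * popstats$c_EI +
    KI * (KI - 1) * g^2 * w^2 * popstats$c_II
  sigma2 <- var_uncorr + cross
  if (any(sigma2 < 0)) stop("negative predicted input variance")
  if (mode == "homogeneous") input_stats(mean(mu), mean(sigma2))
  else input_stats(mu, sigma2)
}

#' Empirical input statistics from a recorded noise-field trace
#'
#' Sample mean and unbiased sample variance of the recorded background input
#' of a single unit.
#'
#' @param noise_field numeric vector of at least 1000 recorded values.
#' @return An [input_stats()].
#' @export
input_stats_empirical <- function(noise_field) {
  noise_field <- as.numeric(noise_field)
  if (length(noise_field) < 1000) stop("need at least 1000 recorded noise-field values")
  input_stats(mean(noise_field), stats::var(noise_field))
}

#' Rescale a sampling network to emulate a target Boltzmann machine
#'
#' With a noise backend supplying background input of mean `mu` and an
#' effective inverse temperature `beta_eff` determined by its strength, the
#' rescaling `w_ij -> (beta/beta_eff) * w_ij`,
#' `b_i -> (beta/beta_eff) * b_i - mu` makes the deterministic network
#' sample from the Boltzmann distribution of the original network at inverse
#' temperature `beta`. The returned network has `beta = 1` (the temperature
#' is absorbed into the weights; the noise supplies the stochasticity).
#'
#' @param net a [sampling_network()].
#' @param beta_target target inverse temperature `beta`.
#' @param beta_eff positive effective inverse temperature of the noise.
#' @param mu mean background input, removed via the bias shift (scalar or
#'   per-unit).
#' @return A rescaled [sampling_network()].
#' @export
rescale_network <- function(net, beta_target = net$beta, beta_eff, mu = 0) {
  stopifnot(inherits(net, "sampling_network"))
  if (beta_eff <= 0) stop("beta_eff must be positive")
  alpha <- beta_target / beta_eff
  sampling_network(alpha * net$W, alpha * net$b - mu, beta = 1)
}

#' Calibrate a noise backend against a target inverse temperature
#'
#' Computes the background-input statistics of the backend (closed form for
#' private and shared noise; mean-field via [selfconsistent_stats()] for
#' network noise, unless `popstats` is supplied), derives the effective
#' inverse temperature from the integral matching, and returns everything
#' needed by [rescale_network()].
#'
#' @param noise a noise backend (see [noise_backends]).
#' @param beta_target target inverse temperature.
#' @param method matching method, `"integral"` or `"taylor"` (only affects
#'   the reported `beta_eff` through the inverse relation used; the integral
#'   inverse is the package's calibration).
#' @param popstats optional precomputed [population_stats] for the network
#'   backend.
#' @param mode homogeneous or heterogeneous input statistics.
#' @return An object of class `calibration_result` with fields `stats`
#'   ([input_stats()]), `beta_eff`, `alpha = beta_target / beta_eff`,
#'   `method`.
#' @export
calibrate_backend <- function(noise, beta_target = 1,
                              method = c("integral", "taylor", "empirical"),
                              popstats = NULL,
                              mode = c("homogeneous", "heterogeneous")) {
  method <- match.arg(method)
  mode <- match.arg(mode)
  stats <- switch(noise$kind,
    intrinsic = input_stats(0, 0),
    private = input_stats(noise$mu, noise$sigma^2),
    shared = input_stats_shared(noise, mode = mode),
    network = {
      if (is.null(popstats)) popstats <- selfconsistent_stats(noise$nnet)
      input_stats_network(noise$projection, popstats, mode = mode)
    },
    stop("unknown backend kind"))
  if (noise$kind == "intrinsic") {
    beta_eff <- beta_target # sampling is exact; no rescaling needed
  } else {
    sigma <- sqrt(stats$sigma2)
    beta_eff <- if (method == "taylor") 2 * sqrt(2) / (sqrt(pi) * sigma)
                else beta_eff_from_sigma(sigma)
  }
  structure(list(stats = stats, beta_eff = beta_eff,
                 alpha = beta_target / beta_eff, method = method,
                 kind = noise$kind),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> backend = %s, method = %s\n", x$kind, x$method))
  cat(sprintf("  mu = %s, sigma2 = %s, beta_eff = %s\n",
              paste(signif(x$stats$mu, 6), collapse = ","),
              paste(signif(x$stats$sigma2, 6), collapse = ","),
              paste(signif(x$beta_eff, 6), collapse = ",")))
  invisible(x)
}

#' @rdname calibrate_backend
#' @param x a `calibration_result`.
#' @param ... unused.
#' @return `glance()` returns a one-row tibble with `kind`, `method`, `mu`,
#'   `sigma2`, `beta_eff`, `alpha`.
#' @export
glance.calibration_result <- function(x, ...) {
  tibble::tibble(kind = x$kind, method = x$method, mu = mean(x$stats$mu),
                 sigma2 = mean(x$stats$sigma2), beta_eff = mean(x$beta_eff),
                 alpha = mean(x$alpha))
}

#' Prepare a calibrated network for simulation with a backend
#'
#' Convenience wrapper: calibrates `noise` against `net$beta` and returns the
#' rescaled network (the identity for intrinsic noise).
#'
#' @inheritParams calibrate_backend
#' @param net the target [sampling_network()].
#' @return A [sampling_network()] ready to be passed to [run_simulation()]
#'   together with `noise`.
#' @export
calibrated_network <- function(net, noise, popstats = NULL,
                               mode = c("homogeneous", "heterogeneous")) {
  mode <- match.arg(mode)
  if (noise$kind == "intrinsic") return(net)
  cal <- calibrate_backend(noise, beta_target = net$beta, popstats = popstats,
                           mode = mode)
  # the weight rescaling is global; per-unit means enter through the bias shift
  rescale_network(net, net$beta, mean(cal$beta_eff), cal$stats$mu)
}
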