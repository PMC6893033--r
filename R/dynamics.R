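#' Activation probability of a binary unit
#'
#' `kind = "logistic"`: `1 / (1 + exp(-beta * h))` — the activation of an
#' intrinsically stochastic unit at inverse temperature `beta`.
#' `kind = "gaussian_erfc"`: `erfc(-(h + mu) / (sqrt(2) * sigma)) / 2` — the
#' noise-averaged activity of a deterministic Heaviside unit receiving
#' additive Gaussian noise `N(mu, sigma^2)`.
#'
#' @param kind `"logistic"` or `"gaussian_erfc"`.
#' @param h input field (vectorized).
#' @param beta inverse temperature (logistic case).
#' @param mu,sigma Gaussian noise parameters (erfc case).
#' @return Activation probabilities, same length as `h`.
#' @export
activation_probability <- function(kind = c("logistic", "gaussian_erfc"), h,
                                   beta = 1, mu = 0, sigma = 1) {
  kind <- match.arg(kind)
  if (kind == "logistic") {
    if (beta <= 0) stop("beta must be positive")
    1 / (1 + exp(-beta * h))
  } else {
    if (sigma <= 0) stop("sigma must be positive")
    # erfc(x)/2 = pnorm(-x * sqrt(2)) evaluated at x = -(h + mu)/(sqrt(2) sigma)
    stats::pnorm((h + mu) / sigma)
  }
}

#' Simulation configuration
#'
#' Every unit (sampling and noise) carries an independent exponential clock
#' with mean update interval `tau`; at each event the scheduled unit
#' recomputes its input field from the current global state and updates its
#' state. The state of `record_subset` is recorded at every update event of a
#' sampling unit at time `t >= T_warmup` (noise-unit updates too when
#' `record_noise_updates = TRUE`).
#'
#' Either `T` (duration in ms) or `n_samples` (number of recorded samples)
#' must be given; with `n_samples`, the duration is set generously and the
#' run stops after exactly `n_samples` recorded events.
#'
#' @param T simulation duration (ms).
#' @param n_samples target number of recorded samples (alternative to `T`).
#' @param tau mean update interval (ms).
#' @param T_warmup warm-up interval excluded from recording (ms).
#' @param seed integer master seed; separate streams are spawned for the
#'   schedule, unit updates, and private-noise draws, so changing the noise
#'   backend does not perturb the event schedule.
#' @param record_subset sampling-unit indices to record (default: all, or
#'   units 1..6 for networks larger than 6 when `n_samples` is used via
#'   sweeps; always explicit here — default all sampling units).
#' @param record_noise_updates also record at noise-unit update events.
#' @param snapshot_every record background-input snapshots every this many
#'   recorded events (0 = off).
#' @param probe_targets sampling-unit indices whose background input is
#'   recorded at snapshots.
#' @param source_cov accumulate the full source covariance matrix over
#'   snapshots (memory `N^2`; keep for moderate `N`).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(T = NULL, n_samples = NULL, tau = 1,
                              T_warmup = 1000, seed = 1L,
                              record_subset = NULL,
                              record_noise_updates = FALSE,
                              snapshot_every = 0L, probe_targets = integer(0),
                              source_cov = FALSE) {
  if (is.null(T) && is.null(n_samples)) stop("give either T or n_samples")
  if (tau <= 0) stop("tau must be positive")
  if (!is.null(T) && (T <= 0 || T_warmup < 0 || T_warmup >= T)) {
    stop("need 0 <= T_warmup < T and T > 0")
  }
  structure(list(T = T, n_samples = n_samples, tau = tau, T_warmup = T_warmup,
                 seed = as.integer(seed), record_subset = record_subset,
                 record_noise_updates = record_noise_updates,
                 snapshot_every = as.integer(snapshot_every),
                 probe_targets = as.integer(probe_targets),
                 source_cov = source_cov),
            class = "simulation_config")
}

#' Run an event-driven simulation
#'
#' Simulates the coupled system of a sampling network and a noise backend
#' (see [noise_backends]) with asynchronous event-driven updates and returns
#' the recorded state trace. Noise units, where present, run concurrently in
#' the same event queue at the same rate `1/tau`; noise delivery is purely
#' feed-forward (no connections from sampling units back to noise units).
#' Initial states are independent fair coin flips at `t = 0`.
#'
#' @param net a [sampling_network()], or `NULL` to simulate a noise backend
#'   on its own (then `record_subset` / `probe_targets` index noise units as
#'   `M + k` with `M = 0`).
#' @param noise a noise backend; default [noise_intrinsic()].
#' @param cfg a [simulation_config()].
#' @return An object of class `state_trace`: `times`, binary `states` matrix
#'   (one row per recorded event), `subset`, `warmup`, `tau`, plus — when
#'   snapshots were requested — `probe_fields`, `source_mean`, `source_cov`,
#'   `n_snapshots`, and always `update_counts` and `final_state`.
#' @export
run_simulation <- function(net, noise = noise_intrinsic(), cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (is.null(net)) {
    net <- structure(list(M = 0L, W = matrix(0, 0, 0), b = numeric(0), beta = 1),
                     class = "sampling_network")
  }
  stopifnot(inherits(net, "sampling_network"), inherits(noise, "noise_backend"))
  M <- net$M

  unit_kind <- switch(noise$kind, intrinsic = 0L, private = 1L, shared = 2L,
                      network = 2L)
  noise_kind <- switch(noise$kind, intrinsic = 0L, private = 0L, shared = 1L,
                       network = 2L)
  priv_mu <- if (noise$kind == "private") noise$mu else 0
  priv_sigma <- if (noise$kind == "private") noise$sigma else 1

  P <- matrix(0, M, 0); noise_bias <- numeric(0); beta_pool <- 1
  A_i <- integer(0); A_j <- integer(0); A_x <- numeric(0)
  if (noise$kind == "shared") {
    P <- noise$projection$m
    noise_bias <- noise$pool$biases
    beta_pool <- noise$pool$beta_pool
  } else if (noise$kind == "network") {
    P <- noise$projection$m
    noise_bias <- noise$nnet$biases
    A_i <- noise$nnet$edges$target - 1L
    A_j <- noise$nnet$edges$source - 1L
    A_x <- noise$nnet$edges$weight
  }
  if (nrow(P) != M) {
    if (M == 0 && noise_kind > 0) {
      P <- matrix(0, 0, length(noise_bias))
    } else {
      stop("projection and sampling network dimensions are inconsistent")
    }
  }

  subset <- cfg$record_subset
  if (is.null(subset)) subset <- seq_len(M)
  subset <- as.integer(subset)
  n_units <- M + length(noise_bias)
  if (length(subset) > 0 && (min(subset) < 1 || max(subset) > n_units)) {
    stop("record_subset out of range")
  }

  max_samples <- 0L
  T_end <- cfg$T
  if (!is.null(cfg$n_samples)) {
    n <- cfg$n_samples
    max_samples <- as.integer(n)
    rec_rate <- if (cfg$record_noise_updates) n_units else M
    if (rec_rate == 0) stop("no recording events possible")
    T_end <- cfg$T_warmup + (n + 6 * sqrt(n) + 50) * cfg$tau / rec_rate
  }

  res <- cpp_run_simulation(net$W, net$b, net$beta, unit_kind, priv_mu,
                            priv_sigma, P, noise_kind, noise_bias, beta_pool,
                            A_i, A_j, A_x, T_end, cfg$tau, cfg$T_warmup,
                            subset - 1L, cfg$record_noise_updates, cfg$seed,
                            cfg$snapshot_every, cfg$probe_targets - 1L,
                            cfg$source_cov, max_samples)
  if (!is.null(cfg$n_samples) && length(res$times) < cfg$n_samples) {
    stop("simulation ended before the requested number of samples was recorded")
  }
  structure(list(times = res$times, states = res$states, subset = subset,
                 warmup = cfg$T_warmup, tau = cfg$tau, T = T_end,
                 seed = cfg$seed, update_counts = res$update_counts,
                 final_state = res$final_state,
                 n_snapshots = res$n_snapshots,
                 probe_fields = res$probe_fields,
                 probe_targets = cfg$probe_targets,
                 source_mean = res$source_mean,
                 source_cov = res$source_cov),
            class = "state_trace")
}

#' @export
print.state_trace <- function(x, ...) {
  cat(sprintf("<state_trace> %d recorded events over %d units (tau = %g ms, warmup = %g ms)\n",
              nrow(x$states), ncol(x$states), x$tau, x$warmup))
  invisible(x)
}

#' Binary state codes of a recorded trace
#'
#' Encodes each recorded state vector as an integer; the first recorded unit
#' is the least-significant bit.
#'
#' @param trace a [state_trace].
#' @return Integer vector of codes in `0 .. 2^m - 1`.
#' @export
state_codes <- function(trace) {
  m <- ncol(trace$states)
  if (m > 30) stop("too many recorded units to encode as integers")
  as.integer(trace$states %*% bitwShiftL(1L, seq_len(m) - 1L))
}
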