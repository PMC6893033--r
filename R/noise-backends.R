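#' Noise backends
#'
#' A noise backend specifies how stochasticity is supplied to the otherwise
#' deterministic units of a sampling network:
#'
#' * `noise_intrinsic()` — units are intrinsically stochastic with a logistic
#'   activation at the network's inverse temperature (Gibbs sampling; the
#'   reference Boltzmann machine).
#' * `noise_private(mu, sigma)` — units are deterministic Heaviside units; at
#'   every update a private Gaussian value `N(mu, sigma^2)` is added to the
#'   input field.
#' * `noise_shared(pool, projection)` — background input from a finite pool
#'   of mutually unconnected stochastic binary units, delivered through a
#'   fixed projection.
#' * `noise_network(nnet, projection)` — background input from a recurrent
#'   deterministic inhibition-dominated network.
#'
#' @name noise_backends
NULL

#' @rdname noise_backends
#' @export
noise_intrinsic <- function() {
  structure(list(kind = "intrinsic"), class = c("noise_intrinsic", "noise_backend"))
}

#' @rdname noise_backends
#' @param mu mean of the private Gaussian noise.
#' @param sigma positive standard deviation of the private Gaussian noise.
#' @export
noise_private <- function(mu = 0, sigma) {
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be positive")
  structure(list(kind = "private", mu = mu, sigma = sigma),
            class = c("noise_private", "noise_backend"))
}

#' @rdname noise_backends
#' @param pool a [make_shared_pool()] object.
#' @param projection a [build_projection()] with source count matching the
#'   pool.
#' @export
noise_shared <- function(pool, projection) {
  stopifnot(inherits(pool, "shared_pool"), inherits(projection, "projection_matrix"))
  if (pool$N != projection$N) stop("pool and projection disagree on N")
  structure(list(kind = "shared", pool = pool, projection = projection),
            class = c("noise_shared", "noise_backend"))
}

#' @rdname noise_backends
#' @param nnet a [make_noise_network()] object.
#' @export
noise_network <- function(nnet, projection) {
  stopifnot(inherits(nnet, "noise_net"), inherits(projection, "projection_matrix"))
  if (nnet$N != projection$N) stop("noise network and projection disagree on N")
  structure(list(kind = "network", nnet = nnet, projection = projection),
            class = c("noise_network", "noise_backend"))
}

#' Build a projection from noise sources onto target units
#'
#' The `N` sources are partitioned once into `ceiling(gamma * N)` excitatory
#' sources (weight `w`) and the rest inhibitory (weight `-g * w`), so Dale's
#' law holds by construction: every source column of the projection is
#' single-signed. Each target draws exactly `K` distinct sources —
#' `round(gamma * K)` excitatory and the remainder inhibitory
#' (`split = "exact"`, the default, which makes the homogeneous input-moment
#' formulas exact), or `K` draws from the pooled ensemble
#' (`split = "random"`).
#'
#' @param N number of sources.
#' @param K in-degree per target (`K <= N`).
#' @param gamma excitatory fraction in (0, 1).
#' @param w excitatory weight (> 0).
#' @param g inhibitory scaling factor (> 0); inhibitory weight is `-g * w`.
#' @param n_targets number of target units.
#' @param seed integer seed.
#' @param split `"exact"` or `"random"` (see Details).
#' @return An object of class `projection_matrix` with the dense
#'   `n_targets x N` weight matrix `m` and the connectivity parameters.
#' @export
build_projection <- function(N, K, gamma, w, g, n_targets, seed = 1L,
                             split = c("exact", "random")) {
  split <- match.arg(split)
  if (K > N) stop("K must not exceed N")
  if (gamma <= 0 || gamma >= 1) stop("gamma must lie in (0, 1)")
  if (w <= 0 || g <= 0) stop("w and g must be positive")
  n_exc <- as.integer(ceiling(gamma * N))
  n_inh <- N - n_exc
  K_E <- as.integer(round(gamma * K))
  K_I <- K - K_E
  if (split == "exact" && (K_E > n_exc || K_I > n_inh)) {
    stop("not enough sources of one sign for the requested exact split")
  }
  m <- matrix(0, n_targets, N)
  with_seed(seed, {
    for (i in seq_len(n_targets)) {
      if (split == "exact") {
        exc <- sample.int(n_exc, K_E)
        inh <- n_exc + sample.int(n_inh, K_I)
      } else {
        src <- sample.int(N, K)
        exc <- src[src <= n_exc]
        inh <- src[src > n_exc]
      }
      m[i, exc] <- w
      m[i, inh] <- -g * w
    }
  })
  structure(list(m = m, N = as.integer(N), K = as.integer(K), gamma = gamma,
                 w = w, g = g, n_exc = n_exc, n_targets = as.integer(n_targets),
                 split = split),
            class = "projection_matrix")
}

#' @export
print.projection_matrix <- function(x, ...) {
  cat(sprintf("<projection_matrix> %d targets x %d sources, K = %d, gamma = %g, w = %g, g = %g\n",
              x$n_targets, x$N, x$K, x$gamma, x$w, x$g))
  invisible(x)
}

#' Shared pool of independent stochastic noise units
#'
#' `N` mutually unconnected, intrinsically stochastic binary units with
#' logistic activation at inverse temperature `beta_pool`. Their average
#' activity is set through their bias via the inverse logistic,
#' `b = (1/beta_pool) * log(z / (1 - z))`.
#'
#' @param N number of pool units.
#' @param gamma excitatory fraction (used by projections drawn on this pool).
#' @param mean_activity target average activity `<z>` in (0, 1).
#' @param beta_pool inverse temperature of the pool units.
#' @return An object of class `shared_pool`.
#' @export
make_shared_pool <- function(N, gamma = 0.8, mean_activity = 0.5, beta_pool = 1) {
  if (mean_activity <= 0 || mean_activity >= 1) {
    stop("mean_activity must lie in (0, 1)")
  }
  if (beta_pool <= 0) stop("beta_pool must be positive")
  bias <- log(mean_activity / (1 - mean_activity)) / beta_pool
  structure(list(N = as.integer(N), gamma = gamma, mean_activity = mean_activity,
                 beta_pool = beta_pool, biases = rep(bias, N)),
            class = "shared_pool")
}

#' Recurrent deterministic noise network
#'
#' `N` Heaviside units with sparse random recurrent connectivity of fixed
#' in-degree `K`, realized with the same excitatory/inhibitory composition
#' and weights (`w`, `-g*w`) as the projections onto the sampling network.
#' Biases cancel the mean recurrent input at `target_activity`. For irregular
#' (non-frozen) activity the connectivity should be inhibition-dominated,
#' `gamma - (1 - gamma) * g < 0`; a warning is issued otherwise.
#'
#' @inheritParams build_projection
#' @param target_activity desired mean activity used for the bias rule.
#' @return An object of class `noise_net` with edge list `edges`
#'   (`target`, `source`, `weight`; 1-based) and `biases`.
#' @export
make_noise_network <- function(N, K, gamma = 0.8, w = 0.05, g = 8,
                               target_activity = 0.5, seed = 1L,
                               split = c("exact", "random")) {
  split <- match.arg(split)
  if (K > N) stop("K must not exceed N")
  if (gamma - (1 - gamma) * g >= 0) {
    warning("connectivity is not inhibition-dominated: gamma - (1 - gamma) * g >= 0")
  }
  n_exc <- as.integer(ceiling(gamma * N))
  n_inh <- N - n_exc
  K_E <- as.integer(round(gamma * K))
  K_I <- K - K_E
  if (split == "exact" && (K_E > n_exc || K_I > n_inh)) {
    stop("not enough sources of one sign for the requested exact split")
  }
  tgt <- integer(0); src <- integer(0); wgt <- numeric(0)
  with_seed(seed, {
    for (k in seq_len(N)) {
      if (split == "exact") {
        # no self-connections: drop self if drawn, redraw once deterministically
        exc <- sample_excluding(n_exc, K_E, if (k <= n_exc) k else 0L)
        inh <- n_exc + sample_excluding(n_inh, K_I, if (k > n_exc) k - n_exc else 0L)
      } else {
        pick <- sample_excluding(N, K, k)
        exc <- pick[pick <= n_exc]
        inh <- pick[pick > n_exc]
      }
      tgt <- c(tgt, rep.int(k, length(exc) + length(inh)))
      src <- c(src, exc, inh)
      wgt <- c(wgt, rep.int(w, length(exc)), rep.int(-g * w, length(inh)))
    }
  })
  mean_w <- K_E * w - K_I * g * w
  biases <- rep(-mean_w * target_activity, N)
  structure(list(N = as.integer(N), K = as.integer(K), gamma = gamma, w = w,
                 g = g, n_exc = n_exc, target_activity = target_activity,
                 edges = data.frame(target = tgt, source = src, weight = wgt),
                 biases = biases, split = split),
            class = "noise_net")
}

# Sample `k` values from 1..n excluding index `excl` (0 = nothing excluded).
sample_excluding <- function(n, k, excl = 0L) {
  if (excl < 1L || excl > n) return(sample.int(n, k))
  out <- sample.int(n - 1L, k)
  out[out >= excl] <- out[out >= excl] + 1L
  out
}

#' @export
print.noise_net <- function(x, ...) {
  cat(sprintf("<noise_net> N = %d, K = %d, gamma = %g, w = %g, g = %g (net coupling %g)\n",
              x$N, x$K, x$gamma, x$w, x$g, x$K * x$w * (x$gamma - (1 - x$gamma) * x$g)))
  invisible(x)
}

#' Detect a dynamical fixed point in a state trace
#'
#' Returns `TRUE` if no recorded unit changes state over the trailing
#' `window` recorded events. Densely connected noise networks (`K` close to
#' `N`) with strong inhibition lock into such fixed points, which destroys
#' their usefulness as noise sources.
#'
#' @param trace a [state_trace] as returned by [run_simulation()].
#' @param window number of trailing events to inspect.
#' @return Logical flag.
#' @export
detect_fixed_point <- function(trace, window) {
  stopifnot(inherits(trace, "state_trace"))
  n <- nrow(trace$states)
  if (n == 0) stop("empty trace")
  if (window > n) stop("window exceeds the number of recorded events")
  tailm <- trace$states[(n - window + 1L):n, , drop = FALSE]
  last <- tailm[window, ]
  all(tailm == rep(last, each = window))
}
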