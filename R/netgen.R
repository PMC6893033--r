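#' Construct a sampling network
#'
#' A sampling network is a Boltzmann-machine-like network of `M` binary units
#' with a symmetric, zero-diagonal weight matrix `W`, biases `b` and a global
#' inverse temperature `beta`. Its stationary state distribution (under the
#' asynchronous update schedule of [run_simulation()] with intrinsic noise) is
#' the Boltzmann distribution returned by [boltzmann_distribution()].
#'
#' @param W square numeric matrix of symmetric weights with zero diagonal.
#' @param b numeric vector of biases, one per unit.
#' @param beta positive inverse temperature.
#' @return An object of class `sampling_network` with fields `M`, `W`, `b`,
#'   `beta`.
#' @export
sampling_network <- function(W, b, beta = 1) {
  W <- as.matrix(W)
  storage.mode(W) <- "double"
  b <- as.numeric(b)
  M <- length(b)
  if (nrow(W) != M || ncol(W) != M) stop("W must be M x M with length(b) == M")
  if (!all(is.finite(W)) || !all(is.finite(b))) stop("weights and biases must be finite")
  if (M > 0 && max(abs(W - t(W))) > 1e-12) stop("W must be symmetric")
  if (M > 0 && any(diag(W) != 0)) stop("W must have zero diagonal")
  if (!is.finite(beta) || beta <= 0) stop("beta must be positive")
  structure(list(M = M, W = W, b = b, beta = beta), class = "sampling_network")
}

#' @export
print.sampling_network <- function(x, ...) {
  cat(sprintf("<sampling_network> M = %d, beta = %g\n", x$M, x$beta))
  cat(sprintf("  mean off-diagonal weight: %.5g\n",
              if (x$M > 1) mean(x$W[upper.tri(x$W)]) else NA_real_))
  cat(sprintf("  bias range: [%.5g, %.5g]\n", min(x$b), max(x$b)))
  invisible(x)
}

#' Generate a random sampling network
#'
#' Off-diagonal weights are drawn from a Beta(`a`, `b`) distribution on
#' \[0, 1\], centred by subtracting its mean `a/(a+b)`, optionally scaled, and
#' shifted to have mean `mu_BM`; the upper triangle is mirrored so the matrix
#' is exactly symmetric with zero diagonal. The bias of each unit is chosen so
#' that, at the desired average activity, it cancels the expected input from
#' the other units: `b_i = -(M-1) * mu_BM * target_activity`
#' (`bias_rule = "cancel"`). The alternative rule
#' `b_i = M * mu_BM * target_activity` is available as
#' `bias_rule = "printed"`.
#'
#' @param M number of units (>= 1).
#' @param mu_BM mean of the off-diagonal weights.
#' @param beta_shape length-2 vector `(a, b)` of Beta shape parameters.
#' @param target_activity desired average unit activity in (0, 1).
#' @param seed integer seed; identical seeds give identical networks.
#' @param beta inverse temperature stored on the network.
#' @param weight_scale multiplier applied to the centred Beta draw before the
#'   `mu_BM` shift; used e.g. to scale weights as `1/sqrt(M)` in network-size
#'   sweeps.
#' @param bias_rule `"cancel"` (default) or `"printed"` (see Details).
#' @return A [sampling_network()].
#' @export
make_random_sampling_network <- function(M, mu_BM = 0, beta_shape = c(2, 2),
                                         target_activity = 0.5, seed = 1L,
                                         beta = 1, weight_scale = 1,
                                         bias_rule = c("cancel", "printed")) {
  bias_rule <- match.arg(bias_rule)
  if (M < 1) stop("M must be >= 1")
  if (!is.finite(mu_BM)) stop("mu_BM must be finite")
  if (target_activity <= 0 || target_activity >= 1) {
    stop("target_activity must lie in (0, 1)")
  }
  a <- beta_shape[1]; bb <- beta_shape[2]
  W <- matrix(0, M, M)
  if (M > 1) {
    n_off <- M * (M - 1) / 2
    draws <- with_seed(seed, rbeta(n_off, a, bb))
    w <- (draws - a / (a + bb)) * weight_scale + mu_BM
    W[upper.tri(W)] <- w
    W <- W + t(W)
  }
  b <- if (bias_rule == "cancel") {
    rep(-(M - 1) * mu_BM * target_activity, M)
  } else {
    rep(M * mu_BM * target_activity, M)
  }
  sampling_network(W, b, beta)
}

#' Distribution table over binary states of a unit subset
#'
#' Holds a normalized probability vector over the `2^m` binary state codes of
#' an ordered subset of `m` units. Unit `subset[1]` is the least-significant
#' bit of the state code.
#'
#' @param probs nonnegative numeric vector of length `2^m`; normalized on
#'   construction.
#' @param subset ordered integer vector of unit indices.
#' @return An object of class `distribution_table`.
#' @export
distribution_table <- function(probs, subset) {
  subset <- as.integer(subset)
  m <- length(subset)
  probs <- as.numeric(probs)
  if (length(probs) != 2^m) stop("probs must have length 2^length(subset)")
  if (any(probs < 0)) stop("probs must be nonnegative")
  s <- sum(probs)
  if (s <= 0) stop("probs must have positive total mass")
  probs <- probs / s
  structure(list(subset = subset, probs = probs), class = "distribution_table")
}

#' @export
print.distribution_table <- function(x, ...) {
  cat(sprintf("<distribution_table> %d units (%s), %d states\n",
              length(x$subset), paste(x$subset, collapse = ","),
              length(x$probs)))
  invisible(x)
}

#' @rdname distribution_table
#' @param x a `distribution_table`.
#' @param ... unused.
#' @return `tidy()` returns a tibble with columns `code`, `state` (binary
#'   string, unit `subset[1]` first) and `prob`.
#' @export
tidy.distribution_table <- function(x, ...) {
  m <- length(x$subset)
  codes <- seq_along(x$probs) - 1L
  bits <- vapply(seq_len(m), function(k) bitwAnd(codes, bitwShiftL(1L, k - 1L)) > 0L,
                 logical(length(codes)))
  state <- apply(matrix(as.integer(bits), ncol = m), 1, paste, collapse = "")
  tibble::tibble(code = codes, state = state, prob = x$probs)
}

#' Exact Boltzmann distribution of a sampling network
#'
#' Enumerates all `2^M` binary states and returns probabilities proportional
#' to `exp(beta/2 * sum_ij w_ij s_i s_j + beta * sum_i b_i s_i)`.
#'
#' @param net a [sampling_network()].
#' @param max_units enumeration cap; networks larger than this raise an error
#'   rather than being silently subsampled.
#' @return A [distribution_table()] over units `1:M`.
#' @export
boltzmann_distribution <- function(net, max_units = 20L) {
  stopifnot(inherits(net, "sampling_network"))
  if (net$M > max_units) {
    stop(sprintf("M = %d exceeds the enumeration cap of %d units", net$M, max_units))
  }
  probs <- cpp_boltzmann_probs(net$W, net$b, net$beta)
  distribution_table(probs, seq_len(net$M))
}

#' Marginal distribution over a unit subset
#'
#' Sums probabilities over the marginalized units; the output keeps the
#' caller-supplied order of `subset`, with `subset[1]` as the
#' least-significant bit.
#'
#' @param dist a [distribution_table()].
#' @param subset units to keep; must be contained in `dist$subset`.
#' @return A [distribution_table()] over `subset`.
#' @export
marginal_distribution <- function(dist, subset) {
  stopifnot(inherits(dist, "distribution_table"))
  subset <- as.integer(subset)
  pos <- match(subset, dist$subset)
  if (anyNA(pos)) stop("subset must be contained in dist$subset")
  m_full <- length(dist$subset)
  m <- length(subset)
  codes <- seq_along(dist$probs) - 1L
  subcode <- integer(length(codes))
  for (k in seq_len(m)) {
    bit <- bitwAnd(codes, bitwShiftL(1L, pos[k] - 1L)) > 0L
    subcode <- subcode + as.integer(bit) * bitwShiftL(1L, k - 1L)
  }
  agg <- rowsum(dist$probs, group = subcode)
  out <- numeric(2^m)
  out[as.integer(rownames(agg)) + 1L] <- agg[, 1]
  distribution_table(out, subset)
}
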