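#' Empirical state distribution of a recorded trace
#'
#' Relative frequency of each binary state code of the recorded subset over
#' all recorded events.
#'
#' @param trace a [state_trace].
#' @param subset units to keep (indices into the original network numbering;
#'   must have been recorded). Defaults to the full recorded subset.
#' @return A [distribution_table()].
#' @export
empirical_distribution <- function(trace, subset = trace$subset) {
  stopifnot(inherits(trace, "state_trace"))
  if (nrow(trace$states) == 0) stop("empty trace")
  pos <- match(subset, trace$subset)
  if (anyNA(pos)) stop("subset was not recorded")
  m <- length(pos)
  codes <- as.integer(trace$states[, pos, drop = FALSE] %*%
                        bitwShiftL(1L, seq_len(m) - 1L))
  counts <- tabulate(codes + 1L, nbins = 2^m)
  distribution_table(counts / sum(counts), subset)
}

#' Kullback-Leibler divergence between two distribution tables
#'
#' `sum_x p(x) * log(p(x) / p*(x))` in nats, with `0 * log 0 = 0`. The
#' reference must be strictly positive wherever `p` has mass; exact
#' Boltzmann references always have full support, while sampled references
#' should be smoothed (see [smooth_distribution()]).
#'
#' @param p empirical [distribution_table()].
#' @param p_star reference [distribution_table()] over the same subset in
#'   the same order.
#' @return KL divergence in nats (nonnegative).
#' @export
kl_divergence <- function(p, p_star) {
  stopifnot(inherits(p, "distribution_table"), inherits(p_star, "distribution_table"))
  if (!identical(p$subset, p_star$subset)) {
    stop("distribution tables must be over the same subset in the same order")
  }
  active <- p$probs > 0
  if (any(p_star$probs[active] <= 0)) {
    stop("reference has zero probability on an observed state; smooth the reference")
  }
  sum(p$probs[active] * log(p$probs[active] / p_star$probs[active]))
}

#' Shannon entropy of a distribution table
#'
#' `-sum p log p` in nats, with `0 * log 0 = 0`. Bounded by `m * log(2)` for
#' `m` units.
#'
#' @param p a [distribution_table()].
#' @return Entropy in nats.
#' @export
entropy <- function(p) {
  stopifnot(inherits(p, "distribution_table"))
  q <- p$probs[p$probs > 0]
  -sum(q * log(q))
}

#' Additive smoothing of a sampled reference distribution
#'
#' Adds `pseudo_count` to every state's (implied) count so a sampled
#' reference has full support; used only when the reference itself must be
#' estimated from samples (e.g. the generative task).
#'
#' @param p a [distribution_table()].
#' @param n_samples the number of samples `p` was estimated from.
#' @param pseudo_count pseudo-count per state.
#' @return A smoothed [distribution_table()].
#' @export
smooth_distribution <- function(p, n_samples, pseudo_count = 1) {
  stopifnot(inherits(p, "distribution_table"))
  counts <- p$probs * n_samples + pseudo_count
  distribution_table(counts / sum(counts), p$subset)
}

#' Pairwise activity correlations of recorded units
#'
#' Pearson correlation coefficients of the recorded binary time series
#' (event-indexed). Zero-variance units give `NA` entries (reported, not
#' silently zeroed).
#'
#' @param trace a [state_trace] with at least two recorded units.
#' @return Correlation matrix with unit diagonal.
#' @export
pairwise_unit_correlations <- function(trace) {
  stopifnot(inherits(trace, "state_trace"))
  s <- trace$states
  if (ncol(s) < 2) stop("need at least two recorded units")
  v <- apply(s, 2, stats::var)
  if (any(v == 0)) warning("zero-variance unit: correlation undefined (NA)")
  suppressWarnings(stats::cor(s))
}

#' Empirical input-correlation decomposition
#'
#' Computes, from background-input snapshots of mutually unconnected probe
#' units, the average input correlation coefficient `rho` and — when the
#' source covariance matrix was accumulated — the decomposition of the pair
#' input covariance into the shared-source term
#' `C_shared = sum_k m_ik m_jk Var(z_k)` and the source-correlation term
#' `C_corr = sum_{k != l} m_ik m_jl Cov(z_k, z_l)`. Because probe fields and
#' source moments are taken at the same snapshot times, the identity
#' `C_in = C_shared + C_corr` holds to floating-point precision.
#'
#' @param trace a [state_trace] from a run with `snapshot_every > 0` and
#'   `probe_targets` set (and `source_cov = TRUE` for the decomposition).
#' @param proj the [build_projection()] used for the probes.
#' @param n_pairs number of probe pairs to average over (sampled without
#'   replacement from all pairs; capped at the number available).
#' @param seed seed for the pair sampling.
#' @return An object of class `correlation_report`: a list with `rho_mean`,
#'   `C_shared`, `C_corr`, `C_in` (pair averages), `n_pairs`, and a tibble
#'   `pairs` with the per-pair quantities.
#' @export
input_correlation_empirical <- function(trace, proj, n_pairs = 100, seed = 1L) {
  stopifnot(inherits(trace, "state_trace"))
  f <- trace$probe_fields
  if (is.null(f) || nrow(f) < 2) stop("trace carries no probe-field snapshots")
  n_probe <- ncol(f)
  if (n_probe < 2) stop("need at least two probe units")
  all_pairs <- utils::combn(n_probe, 2)
  n_pairs <- min(n_pairs, ncol(all_pairs))
  keep <- with_seed(seed, sample.int(ncol(all_pairs), n_pairs))
  pairs <- all_pairs[, keep, drop = FALSE]
  cv <- stats::cov(f)
  have_src <- !is.null(trace$source_cov)
  rows <- lapply(seq_len(n_pairs), function(q) {
    i <- pairs[1, q]; j <- pairs[2, q]
    C_in <- cv[i, j]
    rho <- C_in / sqrt(cv[i, i] * cv[j, j])
    if (have_src) {
      mi <- proj$m[trace$probe_targets[i], ]
      mj <- proj$m[trace$probe_targets[j], ]
      vsrc <- diag(trace$source_cov)
      C_shared <- sum(mi * mj * vsrc)
      C_full <- drop(mi %*% trace$source_cov %*% mj)
      C_corr <- C_full - C_shared
    } else {
      C_shared <- NA_real_; C_corr <- NA_real_
    }
    tibble::tibble(i = i, j = j, C_in = C_in, C_shared = C_shared,
                   C_corr = C_corr, rho = rho)
  })
  tab <- dplyr::bind_rows(rows)
  structure(list(rho_mean = mean(tab$rho), C_shared = mean(tab$C_shared),
                 C_corr = mean(tab$C_corr), C_in = mean(tab$C_in),
                 n_pairs = n_pairs, pairs = tab),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("<correlation_report> %d pairs: rho = %.4g, C_in = %.4g (shared %.4g + corr %.4g)\n",
              x$n_pairs, x$rho_mean, x$C_in, x$C_shared, x$C_corr))
  invisible(x)
}

#' @rdname input_correlation_empirical
#' @param x a `correlation_report`.
#' @param ... unused.
#' @export
tidy.correlation_report <- function(x, ...) x$pairs
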