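#' Synthetic prototype patterns with one-hot labels
#'
#' Builds one binary prototype image per class on a pixel grid, concatenated
#' with a one-hot label block, mirroring the layout of a digit-generation
#' task (e.g. a 12 x 12 grid with 10 classes gives 154-dimensional
#' patterns). Pixels are set independently with probability `density`;
#' classes are redrawn until every pair of prototypes differs in at least
#' 25% of the pixels, so classes are well separated.
#'
#' @param n_classes number of classes (>= 2).
#' @param grid integer `(rows, cols)` of the pixel grid.
#' @param density fraction of active pixels.
#' @param seed integer seed.
#' @param min_separation minimal pairwise Hamming distance as a fraction of
#'   the pixel count.
#' @param max_tries redraw attempts before giving up.
#' @return An object of class `prototype_set`: binary matrix `patterns`
#'   (`n_classes` x `grid_pixels + n_classes`), `grid_pixels`, `n_classes`.
#' @export
make_prototypes <- function(n_classes, grid = c(12, 12), density = 0.4,
                            seed = 1L, min_separation = 0.25,
                            max_tries = 200L) {
  if (n_classes < 2) stop("need at least two classes")
  gp <- as.integer(grid[1] * grid[2])
  min_d <- ceiling(min_separation * gp)
  pix <- with_seed(seed, {
    for (try in seq_len(max_tries)) {
      cand <- matrix(rbinom(n_classes * gp, 1, density), n_classes, gp)
      d <- as.matrix(stats::dist(cand, method = "manhattan"))
      if (min(d[upper.tri(d)]) >= min_d) break
      cand <- NULL
    }
    cand
  })
  if (is.null(pix)) {
    stop("could not achieve the requested prototype separation at this density")
  }
  labels <- diag(n_classes)
  structure(list(patterns = cbind(pix, labels), grid_pixels = gp,
                 n_classes = as.integer(n_classes)),
            class = "prototype_set")
}

#' @export
print.prototype_set <- function(x, ...) {
  cat(sprintf("<prototype_set> %d classes, %d pixels + %d label units (%d-dimensional)\n",
              x$n_classes, x$grid_pixels, x$n_classes, ncol(x$patterns)))
  invisible(x)
}

#' Sample a noisy training batch
#'
#' Classes are drawn i.i.d. from `q`; every pixel entry of the chosen
#' prototype is flipped independently with probability `p_flip` while the
#' label block is left untouched.
#'
#' @param protos a [make_prototypes()] set.
#' @param q class probability vector (normalized internally).
#' @param p_flip pixel flip probability in `[0, 0.5)`.
#' @param n batch size.
#' @param seed integer seed.
#' @return A list with binary matrix `batch` (`n` x pattern length) and
#'   integer vector `classes`.
#' @export
sample_training_batch <- function(protos, q, p_flip = 0.05, n, seed = 1L) {
  stopifnot(inherits(protos, "prototype_set"))
  if (p_flip < 0 || p_flip >= 0.5) stop("p_flip must lie in [0, 0.5)")
  q <- as.numeric(q)
  if (length(q) != protos$n_classes || any(q < 0) || sum(q) <= 0) {
    stop("q must be a valid class distribution")
  }
  q <- q / sum(q)
  gp <- protos$grid_pixels
  with_seed(seed, {
    classes <- sample.int(protos$n_classes, n, replace = TRUE, prob = q)
    batch <- protos$patterns[classes, , drop = FALSE]
    flips <- matrix(rbinom(n * gp, 1, p_flip), n, gp)
    batch[, seq_len(gp)] <- (batch[, seq_len(gp)] + flips) %% 2
    list(batch = batch, classes = classes)
  })
}

#' One CD-1 update of a fully visible Boltzmann machine
#'
#' Positive statistics are taken from the data batch; negative statistics
#' from one full asynchronous Gibbs sweep (each unit updated once in a
#' random order) started at each data vector. Updates are
#' `dw_ij = eta * (<s_i s_j>+ - <s_i s_j>-)` and
#' `db_i = eta * (<s_i>+ - <s_i>-)`; symmetry and the zero diagonal are
#' preserved exactly.
#'
#' @param net a [sampling_network()] with `M` equal to the pattern length.
#' @param batch binary matrix of data vectors (rows).
#' @param eta learning rate (>= 0).
#' @param seed integer seed for the sweep order and Gibbs draws.
#' @return The updated [sampling_network()].
#' @export
cd1_step <- function(net, batch, eta = 0.01, seed = 1L) {
  stopifnot(inherits(net, "sampling_network"))
  batch <- as.matrix(batch)
  storage.mode(batch) <- "integer"
  if (ncol(batch) != net$M) stop("batch vector length must equal M")
  if (eta < 0) stop("eta must be nonnegative")
  if (eta == 0) return(net)
  ord <- with_seed(seed, sample.int(net$M)) - 1L
  neg <- cpp_gibbs_sweep(net$W, net$b, net$beta, batch, ord,
                         child_seed(seed, "cd1"))
  n <- nrow(batch)
  pos_ss <- crossprod(batch) / n
  neg_ss <- crossprod(neg) / n
  dW <- eta * (pos_ss - neg_ss)
  diag(dW) <- 0
  db <- eta * (colMeans(batch) - colMeans(neg))
  sampling_network(net$W + dW, net$b + db, net$beta)
}

#' Empirical distribution of label-block states
#'
#' Distribution over all `2^n_labels` states of the label units of a
#' recorded trace (not restricted to one-hot codes).
#'
#' @param trace a [state_trace].
#' @param label_idx indices of the label units (must be recorded).
#' @return A [distribution_table()] over `label_idx`.
#' @export
label_distribution <- function(trace, label_idx) {
  empirical_distribution(trace, subset = label_idx)
}

# Pool label-state counts over several independent chains (random initial
# conditions); returns a distribution_table. Slowly mixing multimodal nets
# need restarts for unbiased state statistics.
pooled_label_distribution <- function(net, noise, label_idx, n_total,
                                      chains, seed, warmup = 500) {
  per_chain <- ceiling(n_total / chains)
  counts <- 0
  for (ch in seq_len(chains)) {
    cfg <- simulation_config(n_samples = per_chain, T_warmup = warmup,
                             seed = child_seed(seed, "chain", ch),
                             record_subset = label_idx)
    tr <- run_simulation(net, noise, cfg)
    counts <- counts + empirical_distribution(tr)$probs * per_chain
  }
  distribution_table(counts / sum(counts), label_idx)
}

# Winner-take-all class readout: average label activity over windows of
# `window` consecutive recorded samples, argmax per window (ties -> lowest
# index), returning the empirical class distribution.
wta_class_distribution <- function(trace, label_idx, n_classes, window = 200L) {
  pos <- match(label_idx, trace$subset)
  lab <- trace$states[, pos, drop = FALSE]
  n_win <- floor(nrow(lab) / window)
  if (n_win < 1) stop("trace too short for the requested window")
  counts <- numeric(n_classes)
  for (wd in seq_len(n_win)) {
    rows <- ((wd - 1) * window + 1):(wd * window)
    avg <- colMeans(lab[rows, , drop = FALSE])
    counts[which.max(avg)] <- counts[which.max(avg)] + 1
  }
  counts / n_win
}

#' Train a fully visible Boltzmann machine with class rebalancing
#'
#' Outer loop over training sessions: each session draws noisy batches from
#' the prototypes with class-sampling distribution `q` and applies CD-1
#' steps; afterwards the generated class distribution `p_hat` is estimated
#' by Gibbs sampling the current network and reading classes by
#' winner-take-all over the label units. The sampling distribution is then
#' updated multiplicatively, `q(c) <- normalize(q(c) * q_star(c) /
#' max(p_hat(c), floor))` — the minimal rule with fixed point
#' `p_hat = q_star` — and the next session starts.
#'
#' @param net initial [sampling_network()] (pattern-length units).
#' @param protos a [make_prototypes()] set.
#' @param q_star target class distribution.
#' @param sessions number of training sessions.
#' @param steps_per_session CD-1 steps per session.
#' @param batch_size training vectors per CD-1 step.
#' @param eta learning rate.
#' @param p_flip pixel flip probability for training samples.
#' @param eval_samples total recorded Gibbs samples used to estimate `p_hat`
#'   after each session.
#' @param eval_chains independent chains (random initial conditions) the
#'   evaluation samples are split over; multimodal trained distributions mix
#'   slowly, so averaging over restarts is essential for an unbiased
#'   `p_hat`.
#' @param wta_window samples per winner-take-all readout window.
#' @param floor lower bound on `p_hat` entries in the update rule.
#' @param seed integer master seed.
#' @return A list with the trained `net`, the matrix `q_trajectory`
#'   (sessions + 1 rows), and the matrix `p_hat_trajectory`.
#' @export
train_rebalanced <- function(net, protos, q_star, sessions = 20L,
                             steps_per_session = 20L, batch_size = 50L,
                             eta = 0.01, p_flip = 0.05, eval_samples = 30000L,
                             eval_chains = 10L, wta_window = 200L,
                             floor = 1e-3, seed = 1L) {
  stopifnot(inherits(net, "sampling_network"), inherits(protos, "prototype_set"))
  q_star <- q_star / sum(q_star)
  nc <- protos$n_classes
  label_idx <- protos$grid_pixels + seq_len(nc)
  q <- q_star
  q_traj <- matrix(NA_real_, sessions + 1, nc)
  p_traj <- matrix(NA_real_, sessions, nc)
  q_traj[1, ] <- q
  for (s in seq_len(sessions)) {
    for (step in seq_len(steps_per_session)) {
      smp <- sample_training_batch(protos, q, p_flip, batch_size,
                                   seed = child_seed(seed, "batch", s, step))
      net <- cd1_step(net, smp$batch, eta, seed = child_seed(seed, "cd", s, step))
    }
    per_chain <- max(wta_window, ceiling(eval_samples / eval_chains))
    p_hat <- rowMeans(vapply(seq_len(eval_chains), function(ch) {
      cfg <- simulation_config(n_samples = per_chain, T_warmup = 500,
                               seed = child_seed(seed, "eval", s, ch),
                               record_subset = label_idx)
      trace <- run_simulation(net, noise_intrinsic(), cfg)
      wta_class_distribution(trace, label_idx, nc, wta_window)
    }, numeric(nc)))
    if (all(p_hat == 0)) stop("degenerate generated class distribution")
    p_traj[s, ] <- p_hat
    q <- q * q_star / pmax(p_hat, floor)
    q <- q / sum(q)
    q_traj[s + 1, ] <- q
  }
  list(net = net, q_trajectory = q_traj, p_hat_trajectory = p_traj)
}
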