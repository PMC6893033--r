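#' Default noise-source parameters
#'
#' Connectivity and activity parameters shared by the shared-pool and
#' network noise sources (and used to match the private-noise strength):
#' in-degree `K`, source count `N`, excitatory fraction `gamma`, excitatory
#' weight `w`, inhibitory scaling `g`, source mean activity and pool inverse
#' temperature. The defaults give an inhibition-dominated source
#' (`gamma - (1 - gamma) * g = -0.8`) with background-input moments
#' `mu = -4`, `sigma^2 = 1.7` at `K = 200`.
#'
#' @param K in-degree per sampling unit.
#' @param N number of noise sources.
#' @param gamma excitatory fraction.
#' @param w excitatory weight.
#' @param g inhibitory scaling factor.
#' @param mean_activity source mean activity.
#' @param beta_pool pool inverse temperature.
#' @return A named list.
#' @export
noise_params <- function(K = 200L, N = 222L, gamma = 0.8, w = 0.05, g = 8,
                         mean_activity = 0.5, beta_pool = 1) {
  list(K = as.integer(K), N = as.integer(N), gamma = gamma, w = w, g = g,
       mean_activity = mean_activity, beta_pool = beta_pool)
}

# Matched private-noise standard deviation: the shared-pool input fluctuation
# at the same connectivity parameters, so all backends share one beta_eff.
matched_private_sigma <- function(np) {
  sqrt(np$K * np$w^2 * (np$gamma + (1 - np$gamma) * np$g^2) *
         np$mean_activity * (1 - np$mean_activity))
}

#' Build a noise backend from sweep parameters
#'
#' @param kind one of `"intrinsic"`, `"private"`, `"shared"`, `"network"`.
#' @param M number of sampling units (projection targets).
#' @param np a [noise_params()] list.
#' @param seed integer seed for the connectivity realizations.
#' @return A noise backend (see [noise_backends]).
#' @export
build_backend <- function(kind, M, np = noise_params(), seed = 1L) {
  switch(kind,
    intrinsic = noise_intrinsic(),
    private = noise_private(0, matched_private_sigma(np)),
    shared = noise_shared(
      make_shared_pool(np$N, np$gamma, np$mean_activity, np$beta_pool),
      build_projection(np$N, np$K, np$gamma, np$w, np$g, M,
                       seed = child_seed(seed, "proj"))),
    network = noise_network(
      make_noise_network(np$N, np$K, np$gamma, np$w, np$g, np$mean_activity,
                         seed = child_seed(seed, "nnet")),
      build_projection(np$N, np$K, np$gamma, np$w, np$g, M,
                       seed = child_seed(seed, "proj"))),
    stop("unknown backend kind: ", kind))
}

#' Reference distribution over an observed subset
#'
#' Exact marginal Boltzmann distribution when the network is small enough to
#' enumerate; otherwise a smoothed empirical distribution from a long
#' intrinsic-noise (Gibbs) run of the same network.
#'
#' @param net the target [sampling_network()].
#' @param subset observed units.
#' @param max_units enumeration cap.
#' @param n_ref samples for the sampled fallback reference.
#' @param seed seed for the fallback run.
#' @return A [distribution_table()].
#' @export
reference_distribution <- function(net, subset, max_units = 20L,
                                   n_ref = 1e6, seed = 1L) {
  if (net$M <= max_units) {
    marginal_distribution(boltzmann_distribution(net, max_units), subset)
  } else {
    cfg <- simulation_config(n_samples = n_ref, seed = child_seed(seed, "ref"),
                             record_subset = subset)
    tr <- run_simulation(net, noise_intrinsic(), cfg)
    smooth_distribution(empirical_distribution(tr), n_ref)
  }
}

# Calibrate, simulate and evaluate one (net, backend, seed) condition.
# `prefix_samples` additionally evaluates the DKL on leading sub-traces.
eval_condition <- function(net, kind, np, n_samples, seed, subset, ref,
                           popstats = NULL, prefix_samples = NULL) {
  noise <- build_backend(kind, net$M, np, seed)
  simnet <- calibrated_network(net, noise, popstats = popstats)
  cfg <- simulation_config(n_samples = n_samples,
                           seed = child_seed(seed, "sim", kind),
                           record_subset = subset)
  tr <- run_simulation(simnet, noise, cfg)
  emp <- empirical_distribution(tr)
  ns <- if (is.null(prefix_samples)) n_samples else sort(unique(prefix_samples))
  rows <- lapply(ns, function(n) {
    sub <- tr
    sub$states <- tr$states[seq_len(n), , drop = FALSE]
    e <- empirical_distribution(sub)
    tibble::tibble(backend = kind, n_samples = as.numeric(n),
                   dkl = kl_divergence(e, ref), entropy_emp = entropy(e))
  })
  dplyr::bind_rows(rows)
}

#' Sampling error versus sampling duration
#'
#' For each backend and seed, runs the calibrated sampling network for the
#' largest requested sample count and evaluates the KL divergence to the
#' target distribution on leading sub-traces, giving the decay of the
#' sampling error with duration.
#'
#' @param M sampling-network size.
#' @param sample_sizes sample counts at which the error is evaluated.
#' @param backends noise sources to compare.
#' @param seeds one run (network realization + simulation) per seed.
#' @param np a [noise_params()] list.
#' @param mu_BM mean sampling-network weight; default `-0.15 / sqrt(M)`.
#' @param beta target inverse temperature.
#' @param m number of observed units (the recorded subset is `1:m`).
#' @return A tibble, one row per backend x seed x sample count, with class
#'   `noisebm_sweep`.
#' @export
sweep_dkl_vs_samples <- function(M = 20L, sample_sizes = c(1e4, 1e5, 1e6),
                                 backends = c("intrinsic", "private", "shared",
                                              "network"),
                                 seeds = 1:5, np = noise_params(),
                                 mu_BM = -0.15 / sqrt(M), beta = 1, m = 6L) {
  subset <- seq_len(min(m, M))
  n_max <- max(sample_sizes)
  popstats <- if ("network" %in% backends) {
    selfconsistent_stats(list(N = np$N, K = np$K, gamma = np$gamma, w = np$w,
                              g = np$g, target_activity = np$mean_activity))
  } else NULL
  rows <- lapply(seeds, function(sd) {
    net <- make_random_sampling_network(M, mu_BM, seed = child_seed(sd, "net"),
                                        beta = beta)
    ref <- reference_distribution(net, subset, seed = sd)
    dplyr::bind_rows(lapply(backends, function(k) {
      eval_condition(net, k, np, n_max, sd, subset, ref, popstats,
                     prefix_samples = sample_sizes)
    })) |> dplyr::mutate(seed = as.integer(sd), M = as.integer(M))
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("noisebm_sweep", class(out)), x_var = "n_samples")
}

#' Sampling error versus number of noise sources
#'
#' @inheritParams sweep_dkl_vs_samples
#' @param N_values source counts to sweep (in-degree `np$K` fixed).
#' @param n_samples recorded samples per run.
#' @return A tibble with class `noisebm_sweep`.
#' @export
sweep_dkl_vs_N <- function(N_values = c(222L, 400L, 800L, 1600L, 3200L),
                           M = 20L, n_samples = 1e5,
                           backends = c("private", "shared", "network"),
                           seeds = 1:5, np = noise_params(),
                           mu_BM = -0.15 / sqrt(M), beta = 1, m = 6L) {
  subset <- seq_len(min(m, M))
  rows <- lapply(seeds, function(sd) {
    net <- make_random_sampling_network(M, mu_BM, seed = child_seed(sd, "net"),
                                        beta = beta)
    ref <- reference_distribution(net, subset, seed = sd)
    dplyr::bind_rows(lapply(N_values, function(N) {
      npN <- utils::modifyList(np, list(N = as.integer(N)))
      popstats <- if ("network" %in% backends) {
        selfconsistent_stats(list(N = npN$N, K = npN$K, gamma = npN$gamma,
                                  w = npN$w, g = npN$g,
                                  target_activity = npN$mean_activity))
      } else NULL
      dplyr::bind_rows(lapply(backends, function(k) {
        eval_condition(net, k, npN, n_samples, sd, subset, ref, popstats)
      })) |> dplyr::mutate(N = as.integer(N))
    })) |> dplyr::mutate(seed = as.integer(sd), M = as.integer(M))
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("noisebm_sweep", class(out)), x_var = "N")
}

#' Sampling error versus target-distribution entropy
#'
#' Sweeps the inverse temperature `beta` of the target Boltzmann machine
#' (equivalent to a global weight/bias scale); each condition reports the
#' exact entropy of the target marginal alongside the sampling error.
#'
#' @inheritParams sweep_dkl_vs_samples
#' @param beta_values inverse temperatures to sweep.
#' @param n_samples recorded samples per run.
#' @return A tibble with class `noisebm_sweep`.
#' @export
sweep_dkl_vs_entropy <- function(beta_values = c(0.5, 1, 1.5, 2, 3),
                                 M = 20L, n_samples = 3e5,
                                 backends = c("private", "shared", "network"),
                                 seeds = 1:3, np = noise_params(),
                                 mu_BM = -0.15 / sqrt(M), m = 6L) {
  subset <- seq_len(min(m, M))
  popstats <- if ("network" %in% backends) {
    selfconsistent_stats(list(N = np$N, K = np$K, gamma = np$gamma, w = np$w,
                              g = np$g, target_activity = np$mean_activity))
  } else NULL
  rows <- lapply(seeds, function(sd) {
    dplyr::bind_rows(lapply(beta_values, function(bt) {
      net <- make_random_sampling_network(M, mu_BM, seed = child_seed(sd, "net"),
                                          beta = bt)
      ref <- reference_distribution(net, subset, seed = sd)
      dplyr::bind_rows(lapply(backends, function(k) {
        eval_condition(net, k, np, n_samples, sd, subset, ref, popstats)
      })) |> dplyr::mutate(beta = as.numeric(bt), target_entropy = entropy(ref))
    })) |> dplyr::mutate(seed = as.integer(sd), M = as.integer(M))
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("noisebm_sweep", class(out)), x_var = "target_entropy")
}

#' Sampling error versus sampling-network size
#'
#' Sweeps `M` with weights scaled as `1/sqrt(M)` (anchored at the smallest
#' `M`) and mean weight `mu_BM = -0.15 / sqrt(M)`, keeping the entropy of
#' the observed marginal approximately constant.
#'
#' @inheritParams sweep_dkl_vs_samples
#' @param M_values network sizes to sweep.
#' @param n_samples recorded samples per run.
#' @param n_ref samples for sampled references when `M` exceeds the
#'   enumeration cap.
#' @return A tibble with class `noisebm_sweep`.
#' @export
sweep_dkl_vs_M <- function(M_values = c(20L, 50L, 100L), n_samples = 3e5,
                           backends = c("private", "shared", "network"),
                           seeds = 1:3, np = noise_params(), beta = 1,
                           m = 6L, n_ref = 1e6) {
  subset <- seq_len(m)
  popstats <- if ("network" %in% backends) {
    selfconsistent_stats(list(N = np$N, K = np$K, gamma = np$gamma, w = np$w,
                              g = np$g, target_activity = np$mean_activity))
  } else NULL
  M0 <- min(M_values)
  rows <- lapply(seeds, function(sd) {
    dplyr::bind_rows(lapply(M_values, function(M) {
      net <- make_random_sampling_network(
        M, mu_BM = -0.15 / sqrt(M), seed = child_seed(sd, "net"), beta = beta,
        weight_scale = sqrt(M0 / M))
      ref <- reference_distribution(net, subset, n_ref = n_ref, seed = sd)
      dplyr::bind_rows(lapply(backends, function(k) {
        eval_condition(net, k, np, n_samples, sd, subset, ref, popstats)
      })) |> dplyr::mutate(M = as.integer(M), target_entropy = entropy(ref))
    })) |> dplyr::mutate(seed = as.integer(sd))
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("noisebm_sweep", class(out)), x_var = "M")
}

#' Empirical input-correlation sweep over noise-source counts
#'
#' Feeds a set of mutually unconnected probe units from a shared pool or a
#' noise network and measures the average input correlation coefficient
#' `rho` from background-input snapshots.
#'
#' @param N_values source counts to sweep.
#' @param backends `"shared"` and/or `"network"`.
#' @param n_probes number of unconnected probe units.
#' @param n_snapshots background-input snapshots per run.
#' @param snapshot_every recorded events between snapshots.
#' @param np a [noise_params()] list.
#' @param seeds one realization per seed.
#' @param n_pairs probe pairs averaged per run.
#' @param source_cov also accumulate source covariances (enables the
#'   `C_shared`/`C_corr` decomposition; memory `N^2`).
#' @return A tibble (one row per backend x N x seed) with `rho`, `C_in`,
#'   `C_shared`, `C_corr`, class `noisebm_sweep`.
#' @export
sweep_input_correlation <- function(N_values = c(222L, 400L, 800L, 1600L),
                                    backends = c("shared", "network"),
                                    n_probes = 20L, n_snapshots = 20000L,
                                    snapshot_every = 5L, np = noise_params(),
                                    seeds = 1L, n_pairs = 100L,
                                    source_cov = FALSE) {
  probe_net <- sampling_network(matrix(0, n_probes, n_probes),
                                rep(0, n_probes), beta = 1)
  rows <- list()
  for (sd in seeds) {
    for (N in N_values) {
      npN <- utils::modifyList(np, list(N = as.integer(N)))
      for (k in backends) {
        noise <- build_backend(k, n_probes, npN, child_seed(sd, k, N))
        cfg <- simulation_config(n_samples = n_snapshots * snapshot_every,
                                 T_warmup = 500,
                                 seed = child_seed(sd, "sim", k, N),
                                 record_subset = seq_len(n_probes),
                                 snapshot_every = snapshot_every,
                                 probe_targets = seq_len(n_probes),
                                 source_cov = source_cov)
        tr <- run_simulation(probe_net, noise, cfg)
        rep <- input_correlation_empirical(tr, noise$projection,
                                           n_pairs = n_pairs,
                                           seed = child_seed(sd, "pairs"))
        rows[[length(rows) + 1]] <-
          tibble::tibble(backend = k, N = N, seed = sd, rho = rep$rho_mean,
                         C_in = rep$C_in, C_shared = rep$C_shared,
                         C_corr = rep$C_corr, n_pairs = rep$n_pairs)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("noisebm_sweep", class(out)), x_var = "N")
}

#' Generative-task comparison across noise sources
#'
#' Trains a fully visible Boltzmann machine on synthetic prototype patterns
#' with an imbalanced target class distribution (one class `imbalance` times
#' as likely as each of the others) using CD-1 with class rebalancing, then
#' compares the label-state distribution generated under each noise backend
#' against a long intrinsic-noise reference of the same trained network.
#'
#' @param n_classes number of pattern classes.
#' @param grid pixel grid `(rows, cols)`.
#' @param imbalance weight of class 1 relative to each other class.
#' @param backends backends to evaluate against the intrinsic reference.
#' @param seeds evaluation seeds (training itself uses `train_seed`).
#' @param train_seed seed for prototypes and training.
#' @param np a [noise_params()] list.
#' @param n_samples_eval recorded samples per evaluation condition (pooled
#'   over `eval_chains` independent chains with random initial conditions).
#' @param n_ref recorded samples for the intrinsic reference (pooled over
#'   `ref_chains` chains).
#' @param eval_chains,ref_chains numbers of independent restarts pooled per
#'   evaluation / for the reference.
#' @param sessions,steps_per_session,eta,p_flip,eval_samples training
#'   schedule passed to [train_rebalanced()].
#' @return A tibble (backend x seed) of label-state KL divergences, with
#'   attributes `training` (the [train_rebalanced()] result), `class_ratio`
#'   (generated frequency of class 1 over the mean of the others) and
#'   `reference` (the smoothed reference table); class `noisebm_sweep`.
#' @export
sweep_generative <- function(n_classes = 4L, grid = c(6, 6), imbalance = 2,
                             backends = c("private", "shared", "network"),
                             seeds = 1:5, train_seed = 1L,
                             np = noise_params(), n_samples_eval = 2e5,
                             n_ref = 5e5, eval_chains = 5L, ref_chains = 20L,
                             sessions = 20L, steps_per_session = 20L,
                             eta = 0.01, p_flip = 0.05,
                             eval_samples = 60000L) {
  protos <- make_prototypes(n_classes, grid, seed = child_seed(train_seed, "protos"))
  q_star <- c(imbalance, rep(1, n_classes - 1))
  q_star <- q_star / sum(q_star)
  Mtot <- protos$grid_pixels + n_classes
  label_idx <- protos$grid_pixels + seq_len(n_classes)
  init <- sampling_network(matrix(0, Mtot, Mtot), rep(0, Mtot), beta = 1)
  training <- train_rebalanced(init, protos, q_star, sessions = sessions,
                               steps_per_session = steps_per_session,
                               eta = eta, p_flip = p_flip,
                               eval_samples = eval_samples, eval_chains = 20L,
                               seed = train_seed)
  net <- training$net

  ref_raw <- pooled_label_distribution(net, noise_intrinsic(), label_idx,
                                       n_ref, chains = ref_chains,
                                       seed = child_seed(train_seed, "ref"))
  ref <- smooth_distribution(ref_raw, n_ref)
  p_hat <- rowMeans(vapply(seq_len(ref_chains), function(ch) {
    cfg <- simulation_config(n_samples = ceiling(n_ref / ref_chains),
                             T_warmup = 500,
                             seed = child_seed(train_seed, "wta", ch),
                             record_subset = label_idx)
    tr <- run_simulation(net, noise_intrinsic(), cfg)
    wta_class_distribution(tr, label_idx, n_classes)
  }, numeric(n_classes)))
  class_ratio <- p_hat[1] / mean(p_hat[-1])

  popstats <- if ("network" %in% backends) {
    selfconsistent_stats(list(N = np$N, K = np$K, gamma = np$gamma, w = np$w,
                              g = np$g, target_activity = np$mean_activity))
  } else NULL
  rows <- list()
  for (sd in seeds) {
    for (k in backends) {
      noise <- build_backend(k, Mtot, np, child_seed(sd, k))
      simnet <- calibrated_network(net, noise, popstats = popstats)
      emp <- pooled_label_distribution(simnet, noise, label_idx,
                                       n_samples_eval, chains = eval_chains,
                                       seed = child_seed(sd, "gen", k))
      rows[[length(rows) + 1]] <-
        tibble::tibble(backend = k, seed = sd,
                       dkl = kl_divergence(emp, ref))
    }
  }
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("noisebm_sweep", class(out)), x_var = "backend",
            training = training, class_ratio = class_ratio, reference = ref,
            q_star = q_star)
}

#' Run a config-driven experiment
#'
#' Dispatches on `config$experiment` (`"dkl_vs_T"`, `"dkl_vs_N"`,
#' `"dkl_vs_entropy"`, `"dkl_vs_M"`, `"input_correlation"`, `"generative"`)
#' and forwards the remaining entries as arguments to the corresponding
#' sweep function. `config` may be a list or the path to a YAML/JSON file.
#' When `out_dir` is given, the tidy results are written as CSV (one row per
#' condition x seed x backend) together with a JSON manifest of all resolved
#' parameters; re-ingesting the manifest reproduces the run.
#'
#' @param config list or path to a YAML/JSON config file.
#' @param out_dir optional output directory.
#' @return The sweep tibble, invisibly when writing files.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  experiment <- config$experiment
  if (is.null(experiment)) stop("config must name an experiment")
  fun <- switch(experiment,
                dkl_vs_T = sweep_dkl_vs_samples,
                dkl_vs_samples = sweep_dkl_vs_samples,
                dkl_vs_N = sweep_dkl_vs_N,
                dkl_vs_entropy = sweep_dkl_vs_entropy,
                dkl_vs_M = sweep_dkl_vs_M,
                input_correlation = sweep_input_correlation,
                generative = sweep_generative,
                stop("unknown experiment: ", experiment))
  args <- config[setdiff(names(config), c("experiment", "out_dir"))]
  if (!is.null(args$np)) args$np <- do.call(noise_params, as.list(args$np))
  res <- do.call(fun, args)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(as.data.frame(res),
                     file.path(out_dir, paste0(experiment, ".csv")),
                     row.names = FALSE)
    manifest <- c(list(experiment = experiment), args)
    jsonlite::write_json(manifest,
                         file.path(out_dir, paste0(experiment, "_manifest.json")),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(res))
  }
  res
}
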