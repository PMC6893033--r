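#' Serialize networks and noise objects
#'
#' Sampling networks, projections, shared pools and noise networks round-trip
#' losslessly (full double precision) through a JSON container carrying a
#' `kind` tag, dimensions and dense row-major weight lists. Sampling networks
#' additionally round-trip through a delimited-text pair (weights CSV, biases
#' CSV) written with 17 significant digits.
#'
#' @param x object to serialize.
#' @param path file path.
#' @return `write_network_json()` returns `path` invisibly;
#'   `read_network_json()` returns the reconstructed object.
#' @name serialization
NULL

#' @rdname serialization
#' @export
write_network_json <- function(x, path) {
  obj <- if (inherits(x, "sampling_network")) {
    list(kind = "sampling_network", M = x$M, beta = x$beta,
         weights = as.vector(t(x$W)), biases = x$b)
  } else if (inherits(x, "projection_matrix")) {
    list(kind = "projection", n_targets = x$n_targets, N = x$N, K = x$K,
         gamma = x$gamma, w = x$w, g = x$g, n_exc = x$n_exc,
         weights = as.vector(t(x$m)))
  } else if (inherits(x, "shared_pool")) {
    list(kind = "shared_pool", N = x$N, gamma = x$gamma,
         mean_activity = x$mean_activity, beta_pool = x$beta_pool,
         biases = x$biases)
  } else if (inherits(x, "noise_net")) {
    list(kind = "noise_network", N = x$N, K = x$K, gamma = x$gamma, w = x$w,
         g = x$g, n_exc = x$n_exc, target_activity = x$target_activity,
         biases = x$biases, edges_target = x$edges$target,
         edges_source = x$edges$source, edges_weight = x$edges$weight)
  } else {
    stop("unsupported object")
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname serialization
#' @export
read_network_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  switch(o$kind,
    sampling_network = sampling_network(
      matrix(o$weights, o$M, o$M, byrow = TRUE), o$biases, o$beta),
    projection = structure(
      list(m = matrix(o$weights, o$n_targets, o$N, byrow = TRUE),
           N = as.integer(o$N), K = as.integer(o$K), gamma = o$gamma,
           w = o$w, g = o$g, n_exc = as.integer(o$n_exc),
           n_targets = as.integer(o$n_targets), split = "exact"),
      class = "projection_matrix"),
    shared_pool = structure(
      list(N = as.integer(o$N), gamma = o$gamma,
           mean_activity = o$mean_activity, beta_pool = o$beta_pool,
           biases = o$biases),
      class = "shared_pool"),
    noise_network = structure(
      list(N = as.integer(o$N), K = as.integer(o$K), gamma = o$gamma,
           w = o$w, g = o$g, n_exc = as.integer(o$n_exc),
           target_activity = o$target_activity,
           edges = data.frame(target = o$edges_target,
                              source = o$edges_source,
                              weight = o$edges_weight),
           biases = o$biases, split = "exact"),
      class = "noise_net"),
    stop("unknown kind: ", o$kind))
}

#' @rdname serialization
#' @param weights_path,biases_path CSV paths for the delimited-text pair.
#' @param beta inverse temperature to attach on reading.
#' @export
write_network_csv <- function(x, weights_path, biases_path) {
  stopifnot(inherits(x, "sampling_network"))
  wm <- matrix(sprintf("%.17g", x$W), x$M, x$M)
  utils::write.table(wm, weights_path, sep = ",", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  utils::write.table(matrix(sprintf("%.17g", x$b), ncol = 1), biases_path,
                     sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(weights_path)
}

#' @rdname serialization
#' @export
read_network_csv <- function(weights_path, biases_path, beta = 1) {
  W <- as.matrix(utils::read.csv(weights_path, header = FALSE,
                                 colClasses = "numeric"))
  dimnames(W) <- NULL
  b <- utils::read.csv(biases_path, header = FALSE,
                       colClasses = "numeric")[, 1]
  sampling_network(W, b, beta)
}

#' Read a projection from sparse triplets
#'
#' Accepts a data frame or CSV file with columns `target`, `source`,
#' `weight` (1-based indices) and reconstructs a dense projection. Dale's
#' law (single-signed source columns) is validated.
#'
#' @param x data frame or CSV path.
#' @param n_targets,N dimensions of the projection.
#' @param K,gamma,w,g connectivity metadata (inferred from the triplets when
#'   omitted).
#' @return A `projection_matrix`.
#' @export
projection_from_triplets <- function(x, n_targets, N, K = NULL, gamma = NULL,
                                     w = NULL, g = NULL) {
  df <- if (is.character(x)) utils::read.csv(x) else as.data.frame(x)
  stopifnot(all(c("target", "source", "weight") %in% names(df)))
  m <- matrix(0, n_targets, N)
  m[cbind(df$target, df$source)] <- df$weight
  col_sign <- apply(m, 2, function(col) {
    s <- unique(sign(col[col != 0]))
    length(s) <= 1
  })
  if (!all(col_sign)) stop("triplets violate Dale's law (mixed-sign source column)")
  if (is.null(w)) w <- max(df$weight)
  if (is.null(g)) {
    neg <- df$weight[df$weight < 0]
    g <- if (length(neg)) -min(neg) / w else 0
  }
  counts <- tabulate(df$target, nbins = n_targets)
  if (is.null(K)) K <- as.integer(counts[1])
  pos_cols <- which(apply(m, 2, function(col) any(col > 0)))
  n_exc <- if (length(pos_cols)) max(pos_cols) else 0L
  if (is.null(gamma)) gamma <- n_exc / N
  structure(list(m = m, N = as.integer(N), K = as.integer(K), gamma = gamma,
                 w = w, g = g, n_exc = as.integer(n_exc),
                 n_targets = as.integer(n_targets), split = "imported"),
            class = "projection_matrix")
}

#' Write and read a state trace as delimited text
#'
#' Plain-text array container with a documented header (`# key: value` lines
#' carrying subset, tau, duration, warmup and seed) followed by one row per
#' recorded event: the event time (17 significant digits) and the binary
#' state of each recorded unit. Paths ending in `.gz` are compressed
#' transparently. Round-trips exactly.
#'
#' @param trace a [state_trace].
#' @param path output path (`.gz` for compressed text).
#' @return `write_trace()` returns `path` invisibly; `read_trace()` the
#'   reconstructed [state_trace].
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "state_trace"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# subset: ", paste(trace$subset, collapse = ",")),
    paste0("# tau: ", sprintf("%.17g", trace$tau)),
    paste0("# T: ", sprintf("%.17g", trace$T)),
    paste0("# warmup: ", sprintf("%.17g", trace$warmup)),
    paste0("# seed: ", trace$seed)), con)
  rows <- paste(sprintf("%.17g", trace$times),
                apply(trace$states, 1, paste, collapse = ","), sep = ",")
  writeLines(rows, con)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  lines <- readLines(con)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  getv <- function(key) {
    ln <- hdr[startsWith(hdr, paste0("# ", key, ":"))]
    sub(paste0("# ", key, ": "), "", ln)
  }
  subset <- as.integer(strsplit(getv("subset"), ",")[[1]])
  parts <- do.call(rbind, strsplit(body, ","))
  times <- as.numeric(parts[, 1])
  states <- matrix(as.integer(parts[, -1, drop = FALSE]), nrow = length(times))
  structure(list(times = times, states = states, subset = subset,
                 warmup = as.numeric(getv("warmup")),
                 tau = as.numeric(getv("tau")), T = as.numeric(getv("T")),
                 seed = as.integer(getv("seed"))),
            class = "state_trace")
}
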