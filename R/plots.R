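#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Plot a sweep result
#'
#' Draws the KL divergence (or `rho` for input-correlation sweeps) against
#' the swept variable, one colored line per noise backend, averaged over
#' seeds with a ribbon of +/- one standard error. Log scales are used where
#' the corresponding figure-style sweep is conventionally log-scaled.
#'
#' @param object a `noisebm_sweep` tibble.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.noisebm_sweep <- function(object, ...) {
  xv <- attr(object, "x_var")
  yv <- if ("dkl" %in% names(object)) "dkl" else "rho"
  df <- dplyr::summarise(
    dplyr::group_by(object, dplyr::across(dplyr::all_of(c("backend", xv)))),
    mean = mean(.data[[yv]]),
    sem = stats::sd(.data[[yv]]) / sqrt(max(1, dplyr::n())),
    .groups = "drop")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data[[xv]], y = .data$mean,
                                        colour = .data$backend,
                                        fill = .data$backend)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = xv,
                  y = if (yv == "dkl") "D[KL](p, p*) (nats)" else "input correlation") +
    ggplot2::theme_minimal()
  if (is.numeric(object[[xv]]) && xv %in% c("n_samples", "N")) {
    p <- p + ggplot2::scale_x_log10() + ggplot2::scale_y_log10()
  }
  p
}

#' Plot a distribution table
#'
#' Bar chart of state probabilities, optionally against a reference.
#'
#' @param object a [distribution_table()].
#' @param reference optional reference [distribution_table()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.distribution_table <- function(object, reference = NULL, ...) {
  df <- tidy.distribution_table(object)
  df$which <- "empirical"
  if (!is.null(reference)) {
    rf <- tidy.distribution_table(reference)
    rf$which <- "target"
    df <- dplyr::bind_rows(df, rf)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$state, y = .data$prob,
                                   fill = .data$which)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "state", y = "probability") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, size = 6))
}

#' @importFrom ggplot2 autoplot .data
#' @export
ggplot2::autoplot
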