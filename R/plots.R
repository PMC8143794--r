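# ggplot2 visualisations for the package's result types.

#' Plot a coefficient series
#'
#' One line per regressor of (absolute) coefficient magnitude over window
#' centres.
#'
#' @param object A `coef_series` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coef_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$window_center_ms, y = .data$coef, colour = .data$regressor
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "window centre (ms from test stimulus)",
      y = "|coefficient|", colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot a choice trace
#'
#' The 2-D trajectory of input-adaptation magnitude (x) against
#' response-adaptation magnitude (y) over time, one path per input type.
#'
#' @param object A `choice_trace` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.choice_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$x, y = .data$y, colour = .data$input
  )) +
    ggplot2::geom_path(arrow = grid::arrow(length = grid::unit(2, "mm"))) +
    ggplot2::labs(
      x = "input adaptation |coefficient|",
      y = "response adaptation |coefficient|", colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot decoding performance over time
#'
#' @param object A `decoding_series` tibble (optionally with `target`/`context`
#'   columns from [decode_relevant_irrelevant()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.decoding_series <- function(object, ...) {
  aes <- if ("target" %in% names(object)) {
    ggplot2::aes(
      x = .data$window_center_ms, y = .data$score, colour = .data$target
    )
  } else {
    ggplot2::aes(x = .data$window_center_ms, y = .data$score)
  }
  ggplot2::ggplot(object, aes) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "window centre (ms from test stimulus)",
      y = "decoding score (Pearson r)", colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot psychometric curves
#'
#' Fitted probability of choosing the positive pole against signed relevant
#' evidence, one curve per irrelevant-evidence level, faceted by context.
#'
#' @param object A `psychometric_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.psychometric_fit <- function(object, ...) {
  ggplot2::ggplot(object$curves, ggplot2::aes(
    x = .data$rel_strength, y = .data$p_positive,
    colour = factor(.data$irrel_level)
  )) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~context) +
    ggplot2::labs(
      x = "relevant evidence (signed strength)",
      y = "P(choose positive pole)", colour = "irrelevant evidence"
    ) +
    ggplot2::theme_minimal()
}

#' Plot peak-time densities
#'
#' Kernel density of individual peak latencies per regressor (visualisation
#' only).
#'
#' @param object A `peak_estimates` tibble.
#' @param ... Passed to [peak_density()].
#' @return A ggplot object.
#' @export
autoplot.peak_estimates <- function(object, ...) {
  dens <- peak_density(object, ...)
  ggplot2::ggplot(dens, ggplot2::aes(
    x = .data$peak_time_ms, y = .data$density, colour = .data$regressor
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_rug(
      data = object,
      ggplot2::aes(x = .data$peak_time_ms, colour = .data$regressor),
      inherit.aes = FALSE
    ) +
    ggplot2::labs(x = "peak time (ms)", y = "density", colour = NULL) +
    ggplot2::theme_minimal()
}
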