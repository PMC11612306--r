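# ggplot2 views of the three result types: cumulative traces with their
# sigmoid fit, lifetime frequency histograms, and per-condition ECDFs.

#' Plot a cumulative detection trace with its fitted sigmoid
#'
#' @param fit A `cdf_fit` object (carries its trace), or a cumulative trace
#'   tibble.
#' @return A ggplot object.
#' @export
plot_cumulative_trace <- function(fit) {
  if (inherits(fit, "cdf_fit")) {
    trace <- fit$trace
    grid <- tibble::tibble(
      time_s = seq(min(trace$time_s), max(trace$time_s), length.out = 200)
    )
    grid$fitted <- fit$amplitude *
      pnorm((grid$time_s - fit$t0_s) / max(fit$width_s, 1e-12)) +
      fit$baseline_rate_hz * (grid$time_s - trace$time_s[1L])
    ggplot2::ggplot(trace, ggplot2::aes(.data$time_s, .data$cum_count)) +
      ggplot2::geom_step() +
      ggplot2::geom_line(
        data = grid, ggplot2::aes(.data$time_s, .data$fitted),
        colour = "#d95f02", linewidth = 0.8
      ) +
      ggplot2::labs(
        x = "time (s)", y = "cumulative detections",
        subtitle = sprintf("tau = %.2f s, R² = %.3f", fit$tau_s,
                           fit$r_squared)
      ) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(fit, ggplot2::aes(.data$time_s, .data$cum_count)) +
      ggplot2::geom_step() +
      ggplot2::labs(x = "time (s)", y = "cumulative detections") +
      ggplot2::theme_minimal()
  }
}

#' @method autoplot cdf_fit
#' @export
autoplot.cdf_fit <- function(object, ...) {
  plot_cumulative_trace(object)
}

#' Lifetime frequency histogram per condition
#'
#' The distribution-frequency view of gated correlation times; the bin
#' width defaults to the frequency-filter bin width so the plot shows the
#' same histogram the modal-frequency gate operates on.
#'
#' @param set A `lifetime_set` (or data frame with `condition`, `tau_s`).
#' @param bin_width_s Histogram bin width, seconds.
#' @param live_tau_max_s If non-`NULL`, draws the live/fixed discrimination
#'   bound.
#' @return A ggplot object.
#' @export
plot_lifetime_histogram <- function(set, bin_width_s = 2,
                                    live_tau_max_s = NULL) {
  p <- ggplot2::ggplot(set, ggplot2::aes(.data$tau_s, fill = .data$condition)) +
    ggplot2::geom_histogram(binwidth = bin_width_s, boundary = 0,
                            position = "identity", alpha = 0.55) +
    ggplot2::labs(x = "correlation time tau (s)", y = "frequency") +
    ggplot2::theme_minimal()
  if (!is.null(live_tau_max_s)) {
    p <- p + ggplot2::geom_vline(xintercept = live_tau_max_s,
                                 linetype = "dashed")
  }
  p
}

#' Normalized cumulative lifetime distribution per condition
#'
#' @param set A `lifetime_set` (or data frame with `condition`, `tau_s`).
#' @return A ggplot object.
#' @export
plot_lifetime_ecdf <- function(set) {
  ggplot2::ggplot(set, ggplot2::aes(.data$tau_s, colour = .data$condition)) +
    ggplot2::stat_ecdf(linewidth = 0.8) +
    ggplot2::labs(x = "correlation time tau (s)",
                  y = "cumulative fraction") +
    ggplot2::theme_minimal()
}

#' @method autoplot lifetime_set
#' @export
autoplot.lifetime_set <- function(object, type = c("ecdf", "histogram"),
                                  ...) {
  type <- match.arg(type)
  if (type == "ecdf") plot_lifetime_ecdf(object) else
    plot_lifetime_histogram(object, ...)
}
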