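# ggplot2 graphics for traces, events, error histograms and agreement.

#' Plot a signal trace with optional event markers
#'
#' @param trace A [signal_trace()].
#' @param events Optional [gait_events()] drawn as vertical lines colored
#'   by kind.
#' @param xlim Optional time window (s).
#' @return A ggplot object.
#' @export
plot_signal <- function(trace, events = NULL, xlim = NULL) {
  stopifnot(inherits(trace, "signal_trace"))
  df <- tibble(time = trace$time, value = trace$value)
  if (!is.null(xlim)) df <- filter(df, .data$time >= xlim[1], .data$time <= xlim[2])
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(
      x = "time (s)",
      y = sprintf("%s signal (V)", trace_channel(trace))
    ) +
    ggplot2::theme_minimal()
  if (!is.null(events) && nrow(events) > 0L) {
    ev <- tibble(time = events$time, kind = events$kind)
    if (!is.null(xlim)) {
      ev <- filter(ev, .data$time >= xlim[1], .data$time <= xlim[2])
    }
    p <- p + ggplot2::geom_vline(
      data = ev,
      ggplot2::aes(xintercept = .data$time, colour = .data$kind),
      linetype = "dashed", alpha = 0.7
    ) +
      ggplot2::scale_colour_manual(values = c(IC = "#d95f02", SE = "#1b9e77"))
  }
  p
}

#' @export
autoplot.signal_trace <- function(object, events = NULL, xlim = NULL, ...) {
  plot_signal(object, events = events, xlim = xlim)
}

#' Histogram of event-timing errors
#'
#' @param stats An [error_stats()] result.
#' @return A ggplot object.
#' @export
plot_error_histogram <- function(stats) {
  stopifnot(inherits(stats, "event_error_stats"))
  h <- stats$histogram
  ggplot2::ggplot(h, ggplot2::aes(
    x = (.data$lower + .data$upper) / 2,
    y = .data$count
  )) +
    ggplot2::geom_col(
      width = if (nrow(h)) h$upper[1] - h$lower[1] else 1,
      fill = "#4477aa"
    ) +
    ggplot2::labs(x = "timing error (ms)", y = "count") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.event_error_stats <- function(object, ...) {
  plot_error_histogram(object)
}

#' Per-cycle parameter distributions
#'
#' @param params A [compute_cycle_params()] table.
#' @return A ggplot object with one panel per duration parameter.
#' @export
plot_cycle_params <- function(params) {
  long <- params |>
    select(all_of(c("cycle", "tg_ms", "ts_ms", "tw_ms"))) |>
    tidyr::pivot_longer(-"cycle",
      names_to = "parameter",
      values_to = "ms"
    )
  ggplot2::ggplot(long, ggplot2::aes(.data$cycle, .data$ms)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::facet_wrap(~parameter, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "gait cycle", y = "duration (ms)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cycle_params <- function(object, ...) plot_cycle_params(object)

#' Paired-method scatter of gait-cycle durations
#'
#' @param paired Tibble with columns `tg_efs` and `tg_pressure` (ms), as
#'   produced by [run_pipeline()].
#' @return A ggplot object with the identity line overlaid.
#' @export
plot_agreement <- function(paired) {
  ggplot2::ggplot(
    paired,
    ggplot2::aes(.data$tg_pressure, .data$tg_efs)
  ) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.6, size = 0.9) +
    ggplot2::labs(
      x = "foot-pressure Tg (ms)",
      y = "EFS Tg (ms)"
    ) +
    ggplot2::theme_minimal()
}
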