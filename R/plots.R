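#' Ethogram of a behavior trace
#'
#' Activity state over time, with called sleep bouts shaded.
#'
#' @param object A [behavior_trace].
#' @param bouts Optional [call_sleep_bouts()] result to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.behavior_trace <- function(object, bouts = NULL, ...) {
  fps <- trace_fps(object)
  df <- mutate(as_tibble(object), time_s = .data$frame / fps,
               active = as.numeric(.data$state == "active"))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s,
                                        y = .data$active)) +
    ggplot2::geom_step(linewidth = 0.3) +
    ggplot2::scale_y_continuous(breaks = c(0, 1),
                                labels = c("inactive", "active")) +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(bouts) && nrow(bouts) > 0) {
    bb <- mutate(as_tibble(bouts), xmin = .data$start_frame / fps,
                 xmax = .data$end_frame / fps)
    p <- p + ggplot2::geom_rect(
      data = bb,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = -0.1, ymax = 1.1),
      inherit.aes = FALSE, fill = "steelblue", alpha = 0.25)
  }
  p
}

#' Beam-crossing counts of a DAM series
#'
#' @param object A [dam_series].
#' @param channels Channels to facet over (default: all present).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dam_series <- function(object, channels = NULL, ...) {
  df <- as_tibble(object)
  if (!is.null(channels)) df <- filter(df, .data$channel %in% channels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$minute / 60,
                                   y = .data$count)) +
    ggplot2::geom_col(width = 1 / 60) +
    ggplot2::facet_wrap(~channel) +
    ggplot2::labs(x = "time (h)", y = "beam crossings / min") +
    ggplot2::theme_minimal()
}

#' Scatter of per-animal metrics with median and IQR
#'
#' The standard per-group presentation: one dot per animal (or cell),
#' a thick bar at the median and whiskers at Q1 and Q3.
#'
#' @param data Data frame of per-animal metrics.
#' @param value Metric column name.
#' @param group Grouping column name.
#' @return A ggplot object.
#' @export
plot_median_iqr <- function(data, value, group) {
  sums <- data |>
    group_by(.data[[group]]) |>
    summarise(med = median(.data[[value]]),
              q1 = quantile(.data[[value]], 0.25, names = FALSE),
              q3 = quantile(.data[[value]], 0.75, names = FALSE),
              .groups = "drop")
  ggplot2::ggplot(data, ggplot2::aes(x = .data[[group]],
                                     y = .data[[value]])) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, size = 1) +
    ggplot2::geom_errorbar(data = sums,
                           ggplot2::aes(x = .data[[group]], y = NULL,
                                        ymin = .data$q1, ymax = .data$q3),
                           width = 0.2, linewidth = 0.4) +
    ggplot2::geom_errorbar(data = sums,
                           ggplot2::aes(x = .data[[group]], y = NULL,
                                        ymin = .data$med,
                                        ymax = .data$med),
                           width = 0.35, linewidth = 1.1) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
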