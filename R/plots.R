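#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a tuning curve
#'
#' Bin means with the fitted line overlaid.
#'
#' @param object A [fit_tuning_curve()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.tuning_curve <- function(object, ...) {
  p <- ggplot2::ggplot(
    object$bins,
    ggplot2::aes(x = .data$bin_mean_strength, y = .data$bin_mean_count)
  ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = "|delta kappa 3D| (1/mm)",
      y = "spike count / 30 ms",
      title = paste("Tuning curve, touch order", object$order_label)
    ) +
    ggplot2::theme_minimal()
  if (!object$degenerate) {
    p <- p + ggplot2::geom_abline(
      slope = object$slope, intercept = object$intercept,
      linetype = 2
    )
  }
  p
}

#' Plot normalised response attenuation over a touch sequence
#'
#' Per-unit normalised responses (thin lines) with the across-unit mean.
#'
#' @param curve Output of [attenuation_curve()].
#' @return A ggplot object.
#' @export
plot_attenuation <- function(curve) {
  mean_curve <- dplyr::summarise(
    dplyr::group_by(curve, .data$order),
    norm_response = mean(.data$norm_response), .groups = "drop"
  )
  ggplot2::ggplot(
    curve, ggplot2::aes(x = .data$order, y = .data$norm_response)
  ) +
    ggplot2::geom_line(
      ggplot2::aes(group = .data$unit_id),
      colour = "grey70", linewidth = 0.3
    ) +
    ggplot2::geom_line(data = mean_curve, linewidth = 1) +
    ggplot2::labs(
      x = "touch order in trial", y = "response / first-touch response"
    ) +
    ggplot2::theme_minimal()
}

#' Plot an event-aligned PSTH
#'
#' @param h Output of [psth()].
#' @return A ggplot object.
#' @export
plot_psth <- function(h) {
  ggplot2::ggplot(h, ggplot2::aes(x = .data$time_ms, y = .data$rate)) +
    ggplot2::geom_step() +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::labs(x = "time from touch onset (ms)", y = "rate (spikes/s)") +
    ggplot2::theme_minimal()
}

#' Histogram of whisker-specific adaptation indices
#'
#' @param wsa Output of [wsa_analysis()].
#' @return A ggplot object.
#' @export
plot_wsa <- function(wsa) {
  ggplot2::ggplot(wsa, ggplot2::aes(x = .data$index_i)) +
    ggplot2::geom_histogram(binwidth = 0.05, boundary = 0) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "WSA index I", y = "units") +
    ggplot2::theme_minimal()
}
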