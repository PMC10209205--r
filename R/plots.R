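#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a divergence curve with its fitted short-term slope
#'
#' @param object An `lde_fit` from [compute_lde()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lde_fit
#' @export
autoplot.lde_fit <- function(object, ...) {
  cdf <- object$curve
  sel <- cdf$time_strides >= object$fit_range[1] &
    cdf$time_strides <= object$fit_range[2]
  fit <- lm(mean_log_dist ~ time_strides, data = cdf[sel, ])
  ggplot2::ggplot(cdf, ggplot2::aes(.data$time_strides,
                                    .data$mean_log_dist)) +
    ggplot2::geom_line() +
    ggplot2::geom_abline(intercept = coef(fit)[1], slope = coef(fit)[2],
                         linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(
      x = "time (strides)", y = "mean log divergence",
      title = sprintf("Local divergence exponent: %.3f / stride",
                      object$lde)) +
    ggplot2::theme_minimal()
}

#' Bar chart of stepping-regression gains with standard errors
#'
#' @param object A `stepping_fit` from [fit_stepping()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot stepping_fit
#' @export
autoplot.stepping_fit <- function(object, ...) {
  d <- tidy(object)
  d$term <- factor(d$term, levels = state_names())
  ggplot2::ggplot(d, ggplot2::aes(.data$term, .data$estimate)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$estimate - .data$std.error,
                   ymax = .data$estimate + .data$std.error),
      width = 0.3) +
    ggplot2::labs(
      x = NULL, y = "gain",
      title = sprintf("%s stepping regression (R² = %.3f)",
                      toupper(object$direction), object$r_squared)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Percent-gait ensemble plot of a stride channel
#'
#' Mean and +/- 1 SD ribbon of one channel across a set of
#' percent-gait-normalized strides.
#'
#' @param strides A list of `gait_stride` tibbles from
#'   [normalize_percent_gait()].
#' @param channel Channel name, e.g. `"com_z"` or `"vgrf_right"`.
#' @return A ggplot object.
#' @export
plot_stride_ensemble <- function(strides, channel = "com_z") {
  mat <- vapply(strides, function(s) s[[channel]],
                numeric(nrow(strides[[1]])))
  d <- tibble::tibble(
    percent = strides[[1]]$percent,
    mean = rowMeans(mat),
    sd = apply(mat, 1, stats::sd))
  ggplot2::ggplot(d, ggplot2::aes(.data$percent, .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.25, fill = "steelblue") +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "percent gait", y = channel) +
    ggplot2::theme_minimal()
}

#' Margin-of-stability summary plot by condition
#'
#' @param features A per-stride tibble from [gait_features()] with a
#'   `condition` column.
#' @return A ggplot object showing per-condition mean and SD of the FW,
#'   BW and ML margins of stability.
#' @export
plot_mos_summary <- function(features) {
  d <- summarize_gait(features,
                      measures = c("fw_mos", "bw_mos", "ml_mos"))
  ggplot2::ggplot(d, ggplot2::aes(.data$condition, .data$mean,
                                  fill = .data$condition)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$variability,
                   ymax = .data$mean + .data$variability), width = 0.3) +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "margin of stability (m)") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}
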