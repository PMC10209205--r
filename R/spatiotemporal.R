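#' Summarize per-stride gait measures
#'
#' Computes, per grouping (e.g. subject and condition), the mean and the
#' RMS variability (intra-subject sample standard deviation) of the
#' spatiotemporal measures and margins of stability. A single stride in a
#' group yields an undefined variability, reported as `NA`.
#'
#' @param features A per-stride tibble from [gait_features()] (optionally
#'   nondimensionalized with [nondimensionalize_features()]).
#' @param by Character vector of grouping columns (default `"condition"`).
#' @param measures Character vector of measure columns to summarize.
#' @return A tidy tibble: grouping columns, `measure`, `mean`,
#'   `variability`, `n_strides`.
#' @export
#' @examples
#' sim <- simulate_walker(sim_config(n_strides = 8, seed = 3))
#' summarize_gait(gait_features(sim$kin, sim$insole))
summarize_gait <- function(features, by = "condition",
                           measures = c("stride_time", "stance_time",
                                        "speed", "stride_length",
                                        "step_width", "fw_mos", "bw_mos",
                                        "ml_mos")) {
  measures <- intersect(measures, names(features))
  features |>
    tidyr::pivot_longer(dplyr::all_of(measures), names_to = "measure",
                        values_to = "value") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by)), .data$measure) |>
    dplyr::summarise(
      mean = mean(.data$value, na.rm = TRUE),
      variability = sample_stddev(.data$value),
      n_strides = sum(is.finite(.data$value)),
      .groups = "drop") |>
    dplyr::mutate(measure = factor(.data$measure, levels = measures)) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(by)), .data$measure) |>
    dplyr::mutate(measure = as.character(.data$measure))
}
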