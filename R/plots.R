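# Optional visual summaries of the descriptive statistics.

#' Bar chart of period durations
#'
#' Mean period length with SD error bars, for all tests and per stimulus
#' type - how recording time distributes over the baseline and the four pain
#' periods.
#'
#' @param duration_summary Output of [period_duration_summary()].
#' @return A ggplot object.
#' @export
plot_period_durations <- function(duration_summary) {
  ggplot2::ggplot(duration_summary,
                  ggplot2::aes(x = .data$period, y = .data$mean_s)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = pmax(.data$mean_s - .data$sd_s, 0),
                                        ymax = .data$mean_s + .data$sd_s),
                           width = 0.25) +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = "test period", y = "mean duration (s)") +
    ggplot2::theme_minimal()
}

#' Median feature profiles across periods
#'
#' Medians of the standardized features over all rows of each period,
#' P0 included - the visual comparison that separates the corrugator
#' features (rising with the stimulus) from the remaining muscles (high at
#' baseline, dipping at P1, growing again after the pain threshold).
#'
#' @param labelled Standardized labelled feature table.
#' @return A ggplot object.
#' @export
plot_median_profiles <- function(labelled) {
  feature_cols <- intersect(FEATURES, names(labelled))
  long <- tidyr::pivot_longer(labelled[, c("period", feature_cols)],
                              dplyr::all_of(feature_cols),
                              names_to = "feature", values_to = "value")
  med <- dplyr::summarise(dplyr::group_by(long, .data$period, .data$feature),
                          median = median(.data$value), .groups = "drop")
  ggplot2::ggplot(med, ggplot2::aes(x = .data$period, y = .data$median,
                                    group = .data$feature,
                                    colour = .data$feature)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "test period", y = "median standardized feature") +
    ggplot2::theme_minimal()
}
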