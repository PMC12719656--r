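#' Plot per-meal EGL estimates with confidence intervals
#'
#' Point estimates after outlier exclusion with their 95% confidence
#' intervals; the pre-exclusion means are shown as open points.
#'
#' @param object An `egl_result` from [estimate_egl()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.egl_result <- function(object, ...) {
  df <- object$summary
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$meal_code,
                                                      .data$mean_retained))) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci_lo_retained, ymax = .data$ci_hi_retained),
      width = 0.2
    ) +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean_retained), size = 2) +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean_all), shape = 1, size = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "Equivalent glycemic load (g)",
      title = "EGL by test meal",
      subtitle = "filled: outliers excluded (with 95% CI); open: all subjects"
    )
}

#' Plot the simulated EGL distribution
#'
#' Histogram of the individual simulated EGL values, coloured by exclusion
#' status, with the pooled means before and after exclusion marked.
#'
#' @param object An `egl_simulation` from [simulate_egl_population()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.egl_simulation <- function(object, ...) {
  ggplot2::ggplot(object$draws,
                  ggplot2::aes(x = .data$egl, fill = .data$excluded)) +
    ggplot2::geom_histogram(bins = 60, boundary = 0) +
    ggplot2::geom_vline(xintercept = object$pooled_mean_all, linetype = 2) +
    ggplot2::geom_vline(xintercept = object$pooled_mean_retained, linetype = 1) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey35", `TRUE` = "firebrick")) +
    ggplot2::labs(
      x = "Simulated EGL (g)", y = "Subjects", fill = "Excluded",
      title = "Right-skewed EGL ratio distribution",
      subtitle = "dashed: pooled mean before exclusion; solid: after"
    )
}

#' Plot incremental response curves
#'
#' Mean incremental concentration (relative to each curve's fasting
#' baseline) over time, one line per meal.
#'
#' @param data Long measurement table (see [compute_iauc()]).
#' @param analyte Which analyte to plot, default `"glucose"`.
#' @param fasting_times Times defining the baseline, default `c(-5, 0)`.
#' @return A ggplot object.
#' @export
plot_response_curves <- function(data, analyte = "glucose",
                                 fasting_times = c(-5, 0)) {
  keys <- intersect(c("subject_id", "meal_code", "visit", "analyte"), names(data))
  df <- data |>
    as_tibble() |>
    filter(.data$analyte == !!analyte) |>
    group_by(across(all_of(keys))) |>
    mutate(increment = .data$concentration -
             mean(.data$concentration[.data$time_min %in% fasting_times])) |>
    ungroup() |>
    group_by(.data$meal_code, .data$time_min) |>
    summarise(increment = mean(.data$increment), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(.data$time_min, .data$increment,
                                   colour = .data$meal_code)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::labs(
      x = "Time (min)",
      y = paste0("Mean ", analyte, " increment"),
      colour = "Meal"
    )
}
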