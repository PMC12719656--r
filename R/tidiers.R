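#' Tidy an EGL estimation result
#'
#' One row per test meal with the estimates before and after outlier
#' exclusion.
#'
#' @param x An `egl_result` from [estimate_egl()].
#' @param ... Unused.
#' @return A tibble (the per-meal summary).
#' @exportS3Method generics::tidy
#' @export
tidy.egl_result <- function(x, ...) {
  x$summary
}

#' @rdname tidy.egl_result
#' @exportS3Method generics::glance
#' @export
glance.egl_result <- function(x, ...) {
  tibble(
    n_meals = nrow(x$summary),
    n_subjects = length(unique(x$subjects$subject_id)),
    n_excluded_total = sum(x$summary$n_excluded),
    reference_meal = x$reference_meal,
    reference_dose = x$reference_dose,
    outlier_z = x$outlier_z,
    conf_level = x$conf_level
  )
}

#' Tidy an EGL Monte Carlo simulation
#'
#' One row per sequential group with its mean EGL before and after outlier
#' exclusion and the number of exclusions.
#'
#' @param x An `egl_simulation` from [simulate_egl_population()].
#' @param ... Unused.
#' @return A tibble: `group`, `n`, `mean_all`, `mean_retained`, `n_excluded`.
#' @exportS3Method generics::tidy
#' @export
tidy.egl_simulation <- function(x, ...) {
  x$draws |>
    group_by(group = .data$group) |>
    summarise(
      n = dplyr::n(),
      mean_all = mean(.data$egl),
      mean_retained = mean(.data$egl[!.data$excluded]),
      n_excluded = sum(.data$excluded),
      .groups = "drop"
    )
}

#' @rdname tidy.egl_simulation
#' @exportS3Method generics::glance
#' @export
glance.egl_simulation <- function(x, ...) {
  tibble(
    n_subjects = x$n_subjects,
    ref_mean_sim = x$ref_mean_sim, ref_sd_sim = x$ref_sd_sim,
    test_mean_sim = x$test_mean_sim, test_sd_sim = x$test_sd_sim,
    pooled_mean_all = x$pooled_mean_all, pooled_sd_all = x$pooled_sd_all,
    n_excluded = x$n_excluded,
    pooled_mean_retained = x$pooled_mean_retained,
    pooled_sd_retained = x$pooled_sd_retained,
    sd_of_group_means_all = x$sd_of_group_means_all,
    sd_of_group_means_retained = x$sd_of_group_means_retained
  )
}
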