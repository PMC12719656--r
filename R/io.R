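#' Read a long-format measurement CSV
#'
#' Reads and validates the one-dialect measurement CSV (comma-separated,
#' UTF-8, `.` decimal): columns `subject_id`, `meal_code`, `analyte`,
#' `time_min`, `concentration`, one row per finger-stick sample. Malformed
#' files fail with messages naming the offending column or row.
#'
#' @param path Path to the CSV file.
#' @return A validated tibble ready for [compute_iauc()] / [estimate_egl()].
#' @export
read_measurements <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"))
  required <- c("subject_id", "meal_code", "analyte", "time_min", "concentration")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0(path, ": missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  for (col in c("time_min", "concentration")) {
    parsed <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(parsed) & !is.na(raw[[col]]))
    if (length(bad) > 0) {
      abort(paste0(path, ": non-numeric ", col, " in data row(s) ",
                   paste(head(bad, 5), collapse = ", ")))
    }
    raw[[col]] <- parsed
  }
  dup <- duplicated(raw[, c("subject_id", "meal_code", "analyte", "time_min")])
  if (any(dup)) {
    d <- raw[which(dup)[1], ]
    abort(paste0(
      path, ": duplicate sample for subject ", d$subject_id, ", meal ",
      d$meal_code, ", analyte ", d$analyte, ", time ", d$time_min,
      " min (data row ", which(dup)[1], ")"
    ))
  }
  bad_analyte <- setdiff(unique(raw$analyte), c("glucose", "insulin"))
  if (length(bad_analyte) > 0) {
    abort(paste0(path, ": unknown analyte(s): ",
                 paste(bad_analyte, collapse = ", ")))
  }
  raw
}

#' Read a per-serving composition CSV
#'
#' @param path Path to a CSV with columns `meal_code`, `serving_g`,
#'   `energy_kcal`, `fat_g`, `sat_fat_g`, `protein_g`, `total_carb_g`,
#'   `fiber_g`, `allulose_g`.
#' @return A tibble (pass to [derive_carbs()] for the derived fractions).
#' @export
read_composition <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("meal_code", "energy_kcal", "fat_g", "protein_g",
                "total_carb_g", "fiber_g")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0(path, ": missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  raw
}

#' Write a deterministic CSV report
#'
#' Writes results with a fixed column order and rounding so that rewriting
#' the same object yields a byte-identical file. For an [estimate_egl()]
#' result the per-meal summary is written (grams rounded to 1 decimal, as
#' conventionally reported; full precision stays in the R object); for a
#' [simulate_egl_population()] result a one-row summary; a plain data frame
#' is written as-is.
#'
#' @param x An `egl_result`, `egl_simulation`, or data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) UseMethod("write_report")

#' @export
write_report.egl_result <- function(x, path) {
  out <- x$summary |>
    mutate(across(c(
      "mean_all", "sd_all", "sem_all", "ci_lo_all", "ci_hi_all",
      "mean_retained", "sd_retained", "sem_retained",
      "ci_lo_retained", "ci_hi_retained"
    ), ~ round(.x, 1))) |>
    select(
      "meal_code", "n_all", "mean_all", "sd_all", "ci_lo_all", "ci_hi_all",
      "n_excluded", "mean_retained", "sd_retained",
      "ci_lo_retained", "ci_hi_retained"
    )
  readr::write_csv(out, path)
  invisible(path)
}

#' @export
write_report.egl_simulation <- function(x, path) {
  out <- tibble(
    n_subjects = x$n_subjects,
    ref_mean = round(x$ref_mean_sim, 2), ref_sd = round(x$ref_sd_sim, 2),
    test_mean = round(x$test_mean_sim, 2), test_sd = round(x$test_sd_sim, 2),
    egl_mean_all = round(x$pooled_mean_all, 3),
    egl_sd_all = round(x$pooled_sd_all, 3),
    n_excluded = x$n_excluded,
    n_excluded_above = x$n_excluded_above,
    n_excluded_below = x$n_excluded_below,
    egl_mean_retained = round(x$pooled_mean_retained, 3),
    egl_sd_retained = round(x$pooled_sd_retained, 3),
    sd_group_means_all = round(x$sd_of_group_means_all, 3),
    sd_group_means_retained = round(x$sd_of_group_means_retained, 3)
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' @export
write_report.data.frame <- function(x, path) {
  readr::write_csv(as_tibble(x), path)
  invisible(path)
}
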