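#' Fasting baseline of a postprandial time-course
#'
#' The fasting concentration is the arithmetic mean of the samples drawn at
#' the designated fasting times (by default the two pre-meal finger-stick
#' samples at -5 and 0 minutes).
#'
#' @param time_min Numeric vector of sampling times in minutes, strictly
#'   increasing. Pre-meal times are negative or zero.
#' @param concentration Numeric vector of concentrations (mmol/L for glucose,
#'   pmol/L for insulin), same length as `time_min`, non-negative.
#' @param fasting_times Times whose samples define the fasting baseline.
#'   Default `c(-5, 0)`.
#'
#' @return The fasting baseline concentration (scalar).
#' @examples
#' fasting_baseline(c(-5, 0, 15, 30), c(5.4, 5.5, 6.9, 7.8))
#' @export
fasting_baseline <- function(time_min, concentration, fasting_times = c(-5, 0)) {
  check_curve(time_min, concentration, fasting_times)
  mean(concentration[time_min %in% fasting_times])
}

#' Incremental area under the curve above the fasting baseline
#'
#' Computes the incremental area under a concentration-time curve by the
#' trapezoid rule, ignoring any area beneath the fasting baseline. Increments
#' are concentration minus baseline at every time >= 0 (the 0-min increment
#' uses the 0-min sample; the baseline itself stays the fasting mean). Each
#' linear segment whose increment changes sign is clipped exactly at its
#' zero-crossing, so only the regions lying above baseline contribute.
#'
#' @inheritParams fasting_baseline
#' @return The iAUC (concentration x minutes), always >= 0.
#' @examples
#' # constant +1 increment from 15 min on: 0.5*15 + 1*105 = 112.5
#' iauc_above_baseline(c(-5, 0, 15, 30, 45, 60, 90, 120),
#'                     c(5, 5, 6, 6, 6, 6, 6, 6))
#' @seealso [compute_iauc()] for the data-frame interface.
#' @export
iauc_above_baseline <- function(time_min, concentration, fasting_times = c(-5, 0)) {
  base <- fasting_baseline(time_min, concentration, fasting_times)
  post <- time_min >= 0
  if (sum(post) < 2) {
    abort("need at least 2 samples at time >= 0 to integrate")
  }
  t <- time_min[post]
  y <- concentration[post] - base
  n <- length(t)
  area <- 0
  for (i in seq_len(n - 1)) {
    area <- area + segment_area_above_zero(t[i], t[i + 1], y[i], y[i + 1])
  }
  area
}

# Area above zero of one linear segment, clipped at its zero-crossing.
segment_area_above_zero <- function(t1, t2, y1, y2) {
  if (y1 >= 0 && y2 >= 0) {
    return((y1 + y2) / 2 * (t2 - t1))
  }
  if (y1 <= 0 && y2 <= 0) {
    return(0)
  }
  tc <- t1 + (t2 - t1) * y1 / (y1 - y2)
  if (y1 > 0) (tc - t1) * y1 / 2 else (t2 - tc) * y2 / 2
}

#' Per-curve iAUC for a long-format measurement table
#'
#' Takes a long table of finger-stick measurements (one row per sample) and
#' returns one row per curve (subject x meal x analyte, plus a `visit` column
#' if present) with the fasting baseline and the incremental area under the
#' curve. Insulin areas are integrated in pmol x min/L and additionally
#' reported in pmol x h/L (`iauc_reported = iauc / 60`), the conventional
#' reporting unit; glucose is reported unchanged in mmol x min/L.
#'
#' @param data Data frame with columns `subject_id`, `meal_code`, `analyte`
#'   (`"glucose"` or `"insulin"`), `time_min`, `concentration`, and
#'   optionally `visit`.
#' @param fasting_times Times defining the fasting baseline, default `c(-5, 0)`.
#'
#' @return A tibble with columns `subject_id`, `meal_code`, `analyte`
#'   (and `visit` if supplied), `baseline`, `iauc`, `iauc_reported`, `units`.
#' @examples
#' curves <- tibble::tibble(
#'   subject_id = "S01", meal_code = "WB20.8", analyte = "glucose",
#'   time_min = c(-5, 0, 15, 30, 45, 60, 90, 120),
#'   concentration = c(5.4, 5.5, 7.1, 8.0, 7.4, 6.6, 5.8, 5.4)
#' )
#' compute_iauc(curves)
#' @export
compute_iauc <- function(data, fasting_times = c(-5, 0)) {
  required <- c("subject_id", "meal_code", "analyte", "time_min", "concentration")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  keys <- intersect(c("subject_id", "meal_code", "visit", "analyte"), names(data))
  data |>
    as_tibble() |>
    group_by(across(all_of(keys))) |>
    arrange(.data$time_min, .by_group = TRUE) |>
    summarise(
      baseline = with_curve_context(
        fasting_baseline(.data$time_min, .data$concentration, fasting_times),
        cur_group()
      ),
      iauc = with_curve_context(
        iauc_above_baseline(.data$time_min, .data$concentration, fasting_times),
        cur_group()
      ),
      .groups = "drop"
    ) |>
    mutate(
      iauc_reported = ifelse(.data$analyte == "insulin", .data$iauc / 60, .data$iauc),
      units = ifelse(.data$analyte == "insulin", "pmol*h/L", "mmol*min/L")
    )
}

#' Analytical SD of duplicate measures
#'
#' The SD of the difference between duplicate measures, `SDa = sqrt(sum(d^2) /
#' (2 n))`, where `d` are the paired differences and `n` the number of pairs.
#' Used to express day-to-day or analytical variation of repeated glucose
#' measurements and iAUCs.
#'
#' @param differences Numeric vector of paired differences, one per pair.
#' @return The duplicate-measure SD (same units as the measurements).
#' @examples
#' duplicate_sd(c(3, 4)) # sqrt(25/4) = 2.5
#' @export
duplicate_sd <- function(differences) {
  n <- length(differences)
  if (n < 1) abort("at least one pair of duplicates is required")
  sqrt(sum(differences^2) / (2 * n))
}

#' Within-subject coefficient of variation of duplicate measures
#'
#' `100 * SDa / grand mean`, where `SDa` is [duplicate_sd()] of the pairwise
#' differences and the grand mean is taken over all individual measurements.
#'
#' @param first,second Numeric vectors of the first and second measurement of
#'   each pair (e.g. a subject's two reference-bread iAUCs).
#' @return The CV in percent.
#' @examples
#' within_subject_cv(c(80, 100), c(120, 100)) # 20%
#' @export
within_subject_cv <- function(first, second) {
  if (length(first) != length(second)) abort("first and second must pair up")
  if (length(first) < 1) abort("at least one pair is required")
  grand_mean <- mean(c(first, second))
  if (grand_mean == 0) abort("grand mean of the measurements is zero; CV undefined")
  100 * duplicate_sd(first - second) / grand_mean
}

# Re-throw a curve-level error with the subject/meal/analyte it came from.
with_curve_context <- function(expr, group) {
  tryCatch(expr, error = function(e) {
    abort(paste0(
      conditionMessage(e), " [",
      paste(names(group), unlist(lapply(group, as.character)),
            sep = "=", collapse = ", "),
      "]"
    ))
  })
}

# Validate the single-curve invariants shared by the numeric entry points.
check_curve <- function(time_min, concentration, fasting_times) {
  if (length(time_min) != length(concentration)) {
    abort("time_min and concentration must have the same length")
  }
  if (anyNA(time_min) || anyNA(concentration)) {
    abort("missing values in time or concentration")
  }
  if (is.unsorted(time_min, strictly = TRUE)) {
    abort("sampling times must be strictly increasing")
  }
  if (any(concentration < 0)) {
    abort("concentrations must be non-negative")
  }
  absent <- setdiff(fasting_times, time_min)
  if (length(absent) > 0) {
    abort(paste0(
      "missing fasting sample(s) at time ",
      paste(absent, collapse = ", "), " min"
    ))
  }
  invisible(TRUE)
}
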