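#' Per-subject equivalent glycemic load
#'
#' `EGL = reference_dose * T / W`: the grams of available carbohydrate from
#' the reference white bread that elicit the same glucose response as one
#' serving of the test food, where `T` is the test-food iAUC and `W` the
#' subject's (mean) reference-bread iAUC.
#'
#' @param test_iauc Glucose iAUC after the test food (mmol x min/L), >= 0.
#' @param reference_iauc The subject's mean glucose iAUC after the reference
#'   bread (mmol x min/L), > 0.
#' @param reference_dose Grams of available carbohydrate in the reference
#'   bread portion. Default 20.8.
#' @param subject_id Optional label used in error messages.
#' @return EGL in grams. Vectorised over the iAUC arguments.
#' @examples
#' per_subject_egl(21.6, 105.5) # about 4.26 g
#' @export
per_subject_egl <- function(test_iauc, reference_iauc, reference_dose = 20.8,
                            subject_id = NULL) {
  if (reference_dose <= 0) abort("reference_dose must be positive")
  if (any(test_iauc < 0)) abort("test iAUC must be non-negative")
  bad <- which(reference_iauc <= 0)
  if (length(bad) > 0) {
    who <- if (!is.null(subject_id)) {
      paste0(" (subject ", paste(subject_id[bad], collapse = ", "), ")")
    } else ""
    abort(paste0("reference iAUC must be positive", who))
  }
  reference_dose * test_iauc / reference_iauc
}

#' Single-pass z-score outlier exclusion
#'
#' Mean and sample SD are computed once on all values; values lying strictly
#' more than `z` SDs from that mean are flagged as outliers. The rule is
#' applied in a single pass (it is not re-run on the retained values), the
#' convention under which right-skew of ratio-distributed estimates is
#' mitigated without iterated trimming.
#'
#' @param values Numeric vector, length >= 3.
#' @param z Exclusion threshold in SD units, default 1.96.
#' @return A list with `retained` and `excluded` (values, input order
#'   preserved), logical `is_excluded`, and the `mean`, `sd` and absolute
#'   `threshold` used.
#' @examples
#' exclude_outliers(c(rep(5, 9), 15))
#' @export
exclude_outliers <- function(values, z = 1.96) {
  if (length(values) < 3) abort("need at least 3 values to screen for outliers")
  if (z <= 0) abort("z must be positive")
  m <- mean(values)
  s <- sd(values)
  is_excluded <- if (s == 0) {
    rep(FALSE, length(values))
  } else {
    abs(values - m) > z * s
  }
  list(
    retained = values[!is_excluded],
    excluded = values[is_excluded],
    is_excluded = is_excluded,
    mean = m,
    sd = s,
    threshold = z * s
  )
}

#' Mean, SD, SEM and t-based confidence interval
#'
#' Summarises a set of per-subject EGL values (or any small sample) with the
#' two-sided confidence interval `mean +/- t(1 - alpha/2, n - 1) * SD / sqrt(n)`.
#'
#' @param values Numeric vector, length >= 2.
#' @param conf_level Confidence level, default 0.95.
#' @return A one-row tibble: `n`, `mean`, `sd`, `sem`, `ci_lo`, `ci_hi`.
#' @examples
#' summarize_egl(c(3.1, 4.0, 4.4, 5.2))
#' @export
summarize_egl <- function(values, conf_level = 0.95) {
  n <- length(values)
  if (n < 2) abort("need at least 2 values to summarise")
  m <- mean(values)
  s <- sd(values)
  sem <- s / sqrt(n)
  margin <- qt(1 - (1 - conf_level) / 2, df = n - 1) * sem
  tibble(n = n, mean = m, sd = s, sem = sem, ci_lo = m - margin, ci_hi = m + margin)
}

#' Estimate equivalent glycemic load for every test meal in a trial
#'
#' Runs the full EGL chain on a long measurement table or a per-curve iAUC
#' table: per-subject reference mean `W` (averaging repeated reference tests),
#' per-subject `EGL = reference_dose * T / W` for each non-reference meal,
#' single-pass outlier exclusion at `z` SDs, and t-based confidence intervals
#' both before and after exclusion.
#'
#' Repeated tests of the same meal are distinguished either by a `visit`
#' column or by a `#`-suffixed meal code (`WB20.8#1`, `WB20.8#2`); any meal
#' code equal to `reference_meal` or starting with `paste0(reference_meal, "#")`
#' counts as a reference visit.
#'
#' @param data Long measurement table (columns `subject_id`, `meal_code`,
#'   `analyte`, `time_min`, `concentration`) or a per-curve table from
#'   [compute_iauc()] (column `iauc`). Only glucose curves enter the EGL.
#' @param reference_meal Meal code of the reference bread. Default `"WB20.8"`.
#' @param reference_dose Grams of available carbohydrate in the reference
#'   portion. Default 20.8.
#' @param z Outlier threshold in SD units; default 1.96. Set
#'   `exclude = FALSE` to skip exclusion.
#' @param exclude Apply outlier exclusion? Default `TRUE`.
#' @param conf_level Confidence level for the intervals, default 0.95.
#' @param fasting_times Passed to [compute_iauc()] when `data` is raw.
#'
#' @return An object of class `egl_result`: a list with `summary` (one row
#'   per test meal: n, mean/SD/SEM/CI before and after exclusion, number
#'   excluded), `subjects` (per subject x meal: `T`, `W`, `egl`, `excluded`),
#'   and the parameters used. [tidy()], [glance()] and [autoplot()] methods
#'   are provided.
#' @examples
#' cohort <- generate_cohort(cohort_config(
#'   n_subjects = 8, meals = data.frame(meal_code = "BAR", true_egl = 5.2),
#'   seed = 42
#' ))
#' estimate_egl(cohort)
#' @export
estimate_egl <- function(data, reference_meal = "WB20.8", reference_dose = 20.8,
                         z = 1.96, exclude = TRUE, conf_level = 0.95,
                         fasting_times = c(-5, 0)) {
  iauc_tbl <- if ("iauc" %in% names(data)) {
    as_tibble(data)
  } else {
    compute_iauc(data, fasting_times = fasting_times)
  }
  if ("analyte" %in% names(iauc_tbl)) {
    iauc_tbl <- filter(iauc_tbl, .data$analyte == "glucose")
  }
  if (nrow(iauc_tbl) == 0) abort("no glucose curves in the input")

  is_ref <- iauc_tbl$meal_code == reference_meal |
    startsWith(iauc_tbl$meal_code, paste0(reference_meal, "#"))
  if (!any(is_ref)) {
    abort(paste0("reference meal '", reference_meal, "' not found in the data"))
  }

  refs <- iauc_tbl[is_ref, ] |>
    group_by(.data$subject_id) |>
    summarise(W = mean(.data$iauc), n_ref = dplyr::n(), .groups = "drop")
  singles <- refs$subject_id[refs$n_ref == 1]
  if (length(singles) > 0) {
    warn(paste0(
      "subject(s) with a single reference test (their one iAUC is used as W): ",
      paste(singles, collapse = ", ")
    ))
  }

  tests <- iauc_tbl[!is_ref, ] |>
    mutate(meal_code = sub("#[0-9]+$", "", .data$meal_code))
  if (nrow(tests) == 0) abort("no test meals besides the reference in the data")

  all_subjects <- unique(iauc_tbl$subject_id)
  per_meal <- function(meal_tbl, meal) {
    joined <- inner_join(meal_tbl, refs, by = "subject_id")
    missing_subj <- setdiff(all_subjects, meal_tbl$subject_id)
    if (length(missing_subj) > 0) {
      warn(paste0(
        "meal ", meal, ": no data for subject(s) ",
        paste(missing_subj, collapse = ", "), "; skipped"
      ))
    }
    joined <- joined |>
      mutate(egl = per_subject_egl(.data$iauc, .data$W, reference_dose,
                                   subject_id = .data$subject_id))
    if (exclude && nrow(joined) >= 3) {
      exc <- exclude_outliers(joined$egl, z = z)
      joined$excluded <- exc$is_excluded
    } else {
      if (exclude && nrow(joined) < 3) {
        warn(paste0("meal ", meal, ": fewer than 3 subjects; no outlier screening"))
      }
      joined$excluded <- FALSE
    }
    joined |>
      transmute(
        meal_code = meal,
        subject_id = .data$subject_id,
        test_iauc = .data$iauc,
        reference_mean_iauc = .data$W,
        egl = .data$egl,
        excluded = .data$excluded
      )
  }

  subjects <- tests |>
    group_by(.data$meal_code) |>
    group_split() |>
    map(~ per_meal(.x, .x$meal_code[[1]])) |>
    list_rbind()

  summary <- subjects |>
    group_by(.data$meal_code) |>
    group_modify(function(df, key) {
      all_sum <- if (nrow(df) >= 2) {
        summarize_egl(df$egl, conf_level)
      } else {
        tibble(n = 1L, mean = df$egl, sd = NA_real_, sem = NA_real_,
               ci_lo = NA_real_, ci_hi = NA_real_)
      }
      kept <- df$egl[!df$excluded]
      kept_sum <- if (length(kept) >= 2) summarize_egl(kept, conf_level) else all_sum
      tibble(
        n_all = all_sum$n, mean_all = all_sum$mean, sd_all = all_sum$sd,
        sem_all = all_sum$sem, ci_lo_all = all_sum$ci_lo, ci_hi_all = all_sum$ci_hi,
        n_excluded = sum(df$excluded),
        n_retained = kept_sum$n, mean_retained = kept_sum$mean,
        sd_retained = kept_sum$sd, sem_retained = kept_sum$sem,
        ci_lo_retained = kept_sum$ci_lo, ci_hi_retained = kept_sum$ci_hi
      )
    }) |>
    ungroup()

  structure(
    list(
      summary = summary,
      subjects = subjects,
      reference_meal = reference_meal,
      reference_dose = reference_dose,
      outlier_z = if (exclude) z else NA_real_,
      conf_level = conf_level
    ),
    class = "egl_result"
  )
}

#' @export
print.egl_result <- function(x, ...) {
  cat("Equivalent glycemic load (reference ", x$reference_meal,
      ", dose ", x$reference_dose, " g",
      if (!is.na(x$outlier_z)) paste0(", outliers >", x$outlier_z, " SD excluded"),
      ")\n\n", sep = "")
  out <- x$summary |>
    transmute(
      meal = .data$meal_code,
      n = .data$n_all,
      `EGL (all)` = round(.data$mean_all, 1),
      `SEM` = round(.data$sem_all, 1),
      `excl.` = .data$n_excluded,
      `EGL (retained)` = round(.data$mean_retained, 1),
      `95% CI` = sprintf("[%.1f, %.1f]", .data$ci_lo_retained, .data$ci_hi_retained)
    )
  print(as.data.frame(out), row.names = FALSE)
  invisible(x)
}
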