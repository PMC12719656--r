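#' Configuration for a synthetic crossover cohort
#'
#' Collects the generative parameters for [generate_cohort()]: a crossover
#' trial in which every subject tests a reference white-bread portion
#' (twice, by default) and a set of test meals, with lognormal
#' between-subject scaling, lognormal day-to-day variation of the iAUC, and
#' additive analytical noise on each finger-stick sample.
#'
#' The day-to-day CV of the response depends on the dose: small
#' available-carbohydrate doses are relatively much noisier. The CV is
#' `within_subject_cv_lowdose` for true EGL <= `lowdose_egl` grams,
#' `within_subject_cv_ref` at the reference dose, and linearly interpolated
#' in between.
#'
#' @param n_subjects Number of subjects, default 25.
#' @param sampling_times Finger-stick schedule in minutes, default
#'   `c(-5, 0, 15, 30, 45, 60, 90, 120)` (the two pre-meal samples define
#'   the fasting baseline).
#' @param meals Data frame of test meals: `meal_code`, `true_egl` (grams),
#'   and optionally `n_repeats` (default 1).
#' @param reference_code,reference_dose,reference_repeats Reference meal
#'   code, dose in grams, and number of repeated tests; defaults
#'   `"WB20.8"`, 20.8, 2.
#' @param mean_ref_iauc Population mean reference iAUC (mmol x min/L),
#'   default 100.
#' @param between_subject_cv Between-subject CV (%) of the reference iAUC,
#'   default 25.
#' @param within_subject_cv_ref Day-to-day CV (%) at the reference dose,
#'   default 28.6.
#' @param within_subject_cv_lowdose Day-to-day CV (%) at doses of
#'   `lowdose_egl` grams or less, default 60.
#' @param lowdose_egl Dose (grams) at and below which the low-dose CV
#'   applies, default 6.
#' @param fasting_mean Fasting glucose (mmol/L), default 5.45.
#' @param analytical_cv Per-sample additive noise SD as a percent of
#'   `fasting_mean`, default 2.
#' @param seed Optional integer seed.
#' @return A list of class `cohort_config`.
#' @examples
#' cohort_config(meals = data.frame(meal_code = "WB5.2", true_egl = 5.2))
#' @export
cohort_config <- function(n_subjects = 25,
                          sampling_times = c(-5, 0, 15, 30, 45, 60, 90, 120),
                          meals = data.frame(meal_code = "WB5.2", true_egl = 5.2),
                          reference_code = "WB20.8",
                          reference_dose = 20.8,
                          reference_repeats = 2,
                          mean_ref_iauc = 100,
                          between_subject_cv = 25,
                          within_subject_cv_ref = 28.6,
                          within_subject_cv_lowdose = 60,
                          lowdose_egl = 6,
                          fasting_mean = 5.45,
                          analytical_cv = 2,
                          seed = NULL) {
  meals <- as_tibble(meals)
  if (!all(c("meal_code", "true_egl") %in% names(meals))) {
    abort("meals must have columns meal_code and true_egl")
  }
  if (!"n_repeats" %in% names(meals)) meals$n_repeats <- 1L
  cvs <- c(between_subject_cv, within_subject_cv_ref, within_subject_cv_lowdose,
           analytical_cv)
  if (any(cvs < 0)) abort("CVs must be non-negative")
  if (any(meals$true_egl < 0)) abort("true_egl must be non-negative")
  if (reference_dose <= 0) abort("reference_dose must be positive")
  structure(
    list(
      n_subjects = n_subjects, sampling_times = sort(sampling_times),
      meals = meals, reference_code = reference_code,
      reference_dose = reference_dose, reference_repeats = reference_repeats,
      mean_ref_iauc = mean_ref_iauc, between_subject_cv = between_subject_cv,
      within_subject_cv_ref = within_subject_cv_ref,
      within_subject_cv_lowdose = within_subject_cv_lowdose,
      lowdose_egl = lowdose_egl, fasting_mean = fasting_mean,
      analytical_cv = analytical_cv, seed = seed
    ),
    class = "cohort_config"
  )
}

# Dose-dependent day-to-day CV (%): flat below lowdose_egl, flat at and above
# the reference dose, linear in between.
cv_for_dose <- function(true_egl, config) {
  lo <- config$lowdose_egl
  hi <- config$reference_dose
  cv_lo <- config$within_subject_cv_lowdose
  cv_hi <- config$within_subject_cv_ref
  ifelse(
    true_egl <= lo, cv_lo,
    ifelse(true_egl >= hi, cv_hi,
           cv_lo + (cv_hi - cv_lo) * (true_egl - lo) / (hi - lo))
  )
}

# Lognormal multiplier with mean 1 and the given natural-scale CV (%).
lognormal_factor <- function(n, cv_percent) {
  if (cv_percent == 0) return(rep(1, n))
  sigma2 <- log(1 + (cv_percent / 100)^2)
  exp(rnorm(n, -sigma2 / 2, sqrt(sigma2)))
}

# Unimodal incremental template (piecewise linear, peak at 30 min), evaluated
# at arbitrary times in [0, 120]. The shape is a documented convention: the
# analysis only uses the area, never the shape itself.
curve_template <- function(times) {
  knots_t <- c(0, 15, 30, 45, 60, 90, 120)
  knots_y <- c(0, 0.70, 1.00, 0.85, 0.60, 0.25, 0)
  approx(knots_t, knots_y, xout = pmin(pmax(times, 0), 120), rule = 2)$y
}

#' Render a glucose curve with a prescribed incremental area
#'
#' Builds a concentration time-course whose trapezoid-above-baseline iAUC
#' equals `target_iauc` exactly (before noise): increments follow a fixed
#' unimodal template peaking at 30 minutes, scaled to the target area, sitting
#' on the fasting baseline; fasting-time samples equal the fasting level.
#' Optional additive Gaussian noise (SD `noise_sd`) is applied per sample and
#' clipped at zero.
#'
#' @param target_iauc Desired iAUC (mmol x min/L), >= 0.
#' @param times Sampling times in minutes, including the fasting times.
#' @param fasting Fasting concentration (mmol/L).
#' @param noise_sd Additive per-sample noise SD (mmol/L), default 0.
#' @param fasting_times Times rendered at the fasting level, default `c(-5, 0)`.
#' @return A tibble with `time_min` and `concentration`.
#' @examples
#' rc <- render_curve(112.5, c(-5, 0, 15, 30, 45, 60, 90, 120), 5.45)
#' iauc_above_baseline(rc$time_min, rc$concentration)
#' @export
render_curve <- function(target_iauc, times, fasting, noise_sd = 0,
                         fasting_times = c(-5, 0)) {
  if (target_iauc < 0) abort("target_iauc must be non-negative")
  times <- sort(times)
  post <- times > 0
  shape <- curve_template(times[post])
  template_area <- iauc_above_baseline(
    c(fasting_times, times[post]),
    c(rep(0, length(fasting_times)), shape) + 1,
    fasting_times
  ) # baseline 1, increments = shape
  conc <- numeric(length(times))
  conc[!post] <- fasting
  conc[post] <- fasting + shape * (target_iauc / template_area)
  if (noise_sd > 0) {
    conc <- conc + rnorm(length(conc), 0, noise_sd)
    n_clipped <- sum(conc < 0)
    if (n_clipped > 0) {
      inform(paste0(n_clipped, " noisy sample(s) clipped at zero"))
    }
    conc <- pmax(conc, 0)
  }
  tibble(time_min = times, concentration = conc)
}

#' Generate a synthetic crossover cohort of glucose time-courses
#'
#' Simulates the measurement table of a crossover trial with the statistical
#' structure the EGL analysis assumes: each subject carries a lognormal
#' reference-response scale (between-subject variation); each visit's target
#' iAUC is the subject scale times the population reference mean times
#' `true_egl / reference_dose`, times a lognormal day-to-day factor whose CV
#' depends on the dose; the target is rendered as a unimodal curve via
#' [render_curve()] with additive analytical noise.
#'
#' Repeated tests of a meal get `#`-suffixed codes (`WB20.8#1`, `WB20.8#2`),
#' the form [estimate_egl()] recognises as reference visits.
#'
#' @param config A [cohort_config()].
#' @param seed Optional integer seed; overrides `config$seed`.
#' @return A long-format tibble (`subject_id`, `meal_code`, `analyte`,
#'   `time_min`, `concentration`) with the true per-meal EGLs attached as the
#'   `"truth"` attribute (tibble `meal_code`, `true_egl`); retrieve it with
#'   [cohort_truth()].
#' @examples
#' cohort <- generate_cohort(cohort_config(n_subjects = 4, seed = 7))
#' cohort_truth(cohort)
#' @export
generate_cohort <- function(config = cohort_config(), seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  seed <- seed %||% config$seed
  if (!is.null(seed)) set.seed(seed)

  noise_sd <- config$analytical_cv * config$fasting_mean / 100
  visits <- bind_rows(
    tibble(
      meal_code = config$reference_code,
      true_egl = config$reference_dose,
      n_repeats = as.integer(config$reference_repeats)
    ),
    config$meals
  ) |>
    tidyr::uncount(.data$n_repeats, .id = "repeat_idx") |>
    group_by(.data$meal_code) |>
    mutate(
      visit_code = if (dplyr::n() > 1) {
        paste0(.data$meal_code, "#", .data$repeat_idx)
      } else {
        .data$meal_code
      }
    ) |>
    ungroup()

  subjects <- sprintf("S%02d", seq_len(config$n_subjects))
  scales <- lognormal_factor(config$n_subjects, config$between_subject_cv)

  rows <- vector("list", config$n_subjects * nrow(visits))
  k <- 0
  for (i in seq_len(config$n_subjects)) {
    for (v in seq_len(nrow(visits))) {
      cv <- cv_for_dose(visits$true_egl[v], config)
      day <- lognormal_factor(1, cv)
      target <- scales[i] * config$mean_ref_iauc *
        (visits$true_egl[v] / config$reference_dose) * day
      curve <- render_curve(target, config$sampling_times, config$fasting_mean,
                            noise_sd = noise_sd)
      k <- k + 1
      rows[[k]] <- tibble(
        subject_id = subjects[i],
        meal_code = visits$visit_code[v],
        analyte = "glucose",
        time_min = curve$time_min,
        concentration = curve$concentration
      )
    }
  }
  out <- list_rbind(rows)
  attr(out, "truth") <- tibble(
    meal_code = config$meals$meal_code,
    true_egl = config$meals$true_egl
  )
  out
}

#' True per-meal EGLs of a generated cohort
#'
#' @param cohort A measurement table from [generate_cohort()].
#' @return Tibble with `meal_code` and `true_egl`.
#' @export
cohort_truth <- function(cohort) {
  truth <- attr(cohort, "truth")
  if (is.null(truth)) abort("no truth attribute; was this made by generate_cohort()?")
  truth
}
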