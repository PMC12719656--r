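#' Normal draws truncated at zero
#'
#' Draws `n` independent normal variates and replaces negative values by
#' exactly 0, the convention for simulated iAUCs (an incremental area cannot
#' be negative).
#'
#' @param n Number of draws.
#' @param mean,sd Normal mean and SD (`sd >= 0`).
#' @param seed Optional integer seed for reproducibility.
#' @return Numeric vector of length `n`, all values >= 0.
#' @examples
#' draw_truncated_normal(5, 25, 15, seed = 1)
#' @export
draw_truncated_normal <- function(n, mean, sd, seed = NULL) {
  if (n < 1) abort("n must be at least 1")
  if (sd < 0) abort("sd must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  pmax(rnorm(n, mean, sd), 0)
}

#' Monte Carlo simulation of EGL as a ratio of variable glycemic responses
#'
#' Simulates the distribution of per-subject EGL values when the test and
#' reference glycemic responses vary independently from day to day. For each
#' of `n_subjects` simulated subjects a reference iAUC `B20 ~ N(ref_mean,
#' ref_sd)` and a test iAUC `B5 ~ N(test_mean, test_sd)` are drawn (negatives
#' replaced by 0), and `EGL = reference_dose * B5 / B20`. The EGL values are
#' partitioned sequentially into groups of `group_size`; within each group,
#' values more than `outlier_z` SDs from the group's own mean are excluded in
#' a single pass (each group uses its own mean and SD). Because the ratio of
#' two independent normals is right-skewed, exclusion pulls the pooled mean
#' down toward the noise-free value `reference_dose * test_mean / ref_mean`.
#'
#' Reference draws equal to 0 after truncation (probability ~8e-7 per draw at
#' the default configuration) would make the ratio undefined; such subjects
#' are dropped with a warning. A trailing partial group is dropped from the
#' grouped analysis with a warning.
#'
#' @param n_subjects Number of simulated subjects, default 3000.
#' @param ref_mean,ref_sd Reference-response normal parameters, default
#'   100 and 20.8.
#' @param test_mean,test_sd Test-response normal parameters, default 25 and 15.
#' @param reference_dose Grams of available carbohydrate in the reference
#'   portion, default 20.8.
#' @param group_size Size of the sequential groups screened for outliers,
#'   default 25 (one simulated cohort per group).
#' @param outlier_z Exclusion threshold in SD units, default 1.96.
#' @param seed Optional integer seed; a fixed seed makes the whole result
#'   reproducible.
#'
#' @return An object of class `egl_simulation`: a list with
#'   \describe{
#'     \item{draws}{tibble of `b20`, `b5`, `egl`, `group`, `excluded` for the
#'       grouped subjects}
#'     \item{ref_mean_sim, ref_sd_sim, test_mean_sim, test_sd_sim}{moments of
#'       the truncated draws (all `n_subjects` of them)}
#'     \item{pooled_mean_all, pooled_sd_all}{pooled EGL moments before
#'       exclusion}
#'     \item{n_excluded, n_excluded_above, n_excluded_below}{outlier counts}
#'     \item{pooled_mean_retained, pooled_sd_retained}{pooled EGL moments
#'       after exclusion}
#'     \item{group_means_all, group_means_retained}{per-group mean EGL}
#'     \item{sd_of_group_means_all, sd_of_group_means_retained}{SD across the
#'       group means}
#'     \item{group_outlier_counts}{table of groups by number of exclusions}
#'     \item{normality_p}{Shapiro-Wilk p-values for the reference draws, test
#'       draws, and EGL values before/after exclusion}
#'   }
#' @examples
#' sim <- simulate_egl_population(seed = 1)
#' glance(sim)
#' @export
simulate_egl_population <- function(n_subjects = 3000,
                                    ref_mean = 100, ref_sd = 20.8,
                                    test_mean = 25, test_sd = 15,
                                    reference_dose = 20.8,
                                    group_size = 25, outlier_z = 1.96,
                                    seed = NULL) {
  if (n_subjects < 1) abort("n_subjects must be at least 1")
  if (ref_sd < 0 || test_sd < 0) abort("SDs must be non-negative")
  if (!is.null(seed)) set.seed(seed)

  b20 <- pmax(rnorm(n_subjects, ref_mean, ref_sd), 0)
  b5 <- pmax(rnorm(n_subjects, test_mean, test_sd), 0)
  if (all(b20 == 0)) abort("all reference draws are zero; EGL undefined")

  keep <- b20 > 0
  if (any(!keep)) {
    warn(paste0(sum(!keep), " subject(s) with a zero reference draw dropped"))
  }
  egl <- reference_dose * b5[keep] / b20[keep]

  n_kept <- length(egl)
  n_groups <- n_kept %/% group_size
  if (n_kept %% group_size != 0) {
    if (n_kept == n_subjects) {
      warn(paste0(
        "n_subjects is not a multiple of group_size; dropping the trailing ",
        n_kept %% group_size, " value(s) from the grouped analysis"
      ))
    }
    egl_grouped <- egl[seq_len(n_groups * group_size)]
  } else {
    egl_grouped <- egl
  }
  group <- rep(seq_len(n_groups), each = group_size)

  excluded <- logical(length(egl_grouped))
  group_means_all <- numeric(n_groups)
  group_means_retained <- numeric(n_groups)
  for (g in seq_len(n_groups)) {
    idx <- which(group == g)
    exc <- exclude_outliers(egl_grouped[idx], z = outlier_z)
    excluded[idx] <- exc$is_excluded
    group_means_all[g] <- exc$mean
    group_means_retained[g] <- mean(exc$retained)
  }

  retained <- egl_grouped[!excluded]
  above <- sum(excluded & egl_grouped > group_means_all[group])
  counts_per_group <- tapply(excluded, group, sum)
  group_outlier_counts <- table(factor(counts_per_group,
                                       levels = 0:max(counts_per_group)))

  structure(
    list(
      draws = tibble(
        b20 = b20[keep][seq_along(egl_grouped)],
        b5 = b5[keep][seq_along(egl_grouped)],
        egl = egl_grouped,
        group = group,
        excluded = excluded
      ),
      n_subjects = n_subjects,
      ref_mean_sim = mean(b20), ref_sd_sim = sd(b20),
      test_mean_sim = mean(b5), test_sd_sim = sd(b5),
      pooled_mean_all = mean(egl), pooled_sd_all = sd(egl),
      n_excluded = sum(excluded),
      n_excluded_above = above,
      n_excluded_below = sum(excluded) - above,
      pooled_mean_retained = mean(retained),
      pooled_sd_retained = sd(retained),
      group_means_all = group_means_all,
      group_means_retained = group_means_retained,
      sd_of_group_means_all = sd(group_means_all),
      sd_of_group_means_retained = sd(group_means_retained),
      group_outlier_counts = group_outlier_counts,
      normality_p = c(
        ref_draws = normality_p(b20),
        test_draws = normality_p(b5),
        egl_all = normality_p(egl_grouped),
        egl_retained = normality_p(retained)
      ),
      reference_dose = reference_dose,
      group_size = group_size,
      outlier_z = outlier_z
    ),
    class = "egl_simulation"
  )
}

#' @export
print.egl_simulation <- function(x, ...) {
  cat("EGL Monte Carlo simulation (", x$n_subjects, " subjects, groups of ",
      x$group_size, ")\n", sep = "")
  cat(sprintf("  reference draws: mean %.1f, SD %.1f\n", x$ref_mean_sim, x$ref_sd_sim))
  cat(sprintf("  test draws:      mean %.1f, SD %.1f\n", x$test_mean_sim, x$test_sd_sim))
  cat(sprintf("  EGL before exclusion: %.2f +/- %.2f g\n",
              x$pooled_mean_all, x$pooled_sd_all))
  cat(sprintf("  excluded: %d (%d above, %d below the group means)\n",
              x$n_excluded, x$n_excluded_above, x$n_excluded_below))
  cat(sprintf("  EGL after exclusion:  %.2f +/- %.2f g\n",
              x$pooled_mean_retained, x$pooled_sd_retained))
  cat(sprintf("  SD of group means: %.2f (all), %.2f (retained)\n",
              x$sd_of_group_means_all, x$sd_of_group_means_retained))
  invisible(x)
}

#' Goodness-of-fit p-value against normality
#'
#' Shapiro-Wilk for up to 5000 values; for larger samples the
#' Anderson-Darling test ([nortest::ad.test()]) is used, since Shapiro-Wilk
#' is not defined beyond that size. Constant input returns p = 1 with a
#' warning (any normal with SD 0 fits it). The p-value is meant for
#' qualitative threshold checks, not as an exact reproducible statistic.
#'
#' @param values Numeric vector, length >= 8.
#' @return p-value in `[0, 1]`.
#' @examples
#' normality_p(rnorm(100))
#' @export
normality_p <- function(values) {
  if (length(values) < 8) abort("need at least 8 values for a normality test")
  if (sd(values) == 0) {
    warn("constant input; normality p-value reported as 1")
    return(1)
  }
  if (length(values) <= 5000) {
    shapiro.test(values)$p.value
  } else {
    nortest::ad.test(values)$p.value
  }
}

#' Pearson chi-square test on a 2x2 table
#'
#' One-degree-of-freedom Pearson chi-square without continuity correction,
#' e.g. for comparing the simulated outlier proportion with the observed one.
#'
#' @param a,b First row counts; `c`,`d` second row counts.
#' @return A one-row tibble: `statistic`, `df`, `p_value`.
#' @examples
#' two_by_two_chi_square(131, 2869, 11, 189)
#' @export
two_by_two_chi_square <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0)) abort("counts must be non-negative")
  tab <- matrix(counts, nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("a row or column total is zero; chi-square undefined")
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  tibble(
    statistic = unname(ct$statistic),
    df = unname(ct$parameter),
    p_value = ct$p.value
  )
}
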