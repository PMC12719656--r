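test_that("per-subject EGL is the dose-scaled iAUC ratio", {
  expect_equal(per_subject_egl(100, 100), 20.8)
  expect_equal(per_subject_egl(0, 100), 0)
  expect_equal(per_subject_egl(21.6, 105.5), 20.8 * 21.6 / 105.5)
  expect_equal(round(per_subject_egl(21.6, 105.5), 2), 4.26)
  # identity: test equal to reference returns the dose, any dose
  for (w in c(1, 40, 105.5)) {
    expect_equal(per_subject_egl(w, w, reference_dose = 12.3), 12.3)
  }
  expect_error(per_subject_egl(10, 0, subject_id = "S09"), "S09")
  expect_error(per_subject_egl(10, 100, reference_dose = 0), "positive")
})

test_that("outlier exclusion is single-pass with a strict threshold", {
  # zero SD: nothing excluded
  res <- exclude_outliers(rep(5, 4))
  expect_length(res$excluded, 0)
  expect_equal(res$retained, rep(5, 4))

  # mean 6, sd sqrt(10): 15 is beyond 1.96 SD, the nines stay
  res <- exclude_outliers(c(rep(5, 9), 15))
  expect_equal(res$excluded, 15)
  expect_equal(res$retained, rep(5, 9))

  # |10 - 2.8| = 7.2 <= 1.96 * 4.025: retained (strict inequality)
  res <- exclude_outliers(c(1, 1, 1, 1, 10))
  expect_length(res$excluded, 0)

  expect_error(exclude_outliers(c(1, 2)), "at least 3")
})

test_that("exclusion partition matches a brute-force recheck", {
  set.seed(303)
  for (i in 1:50) {
    v <- 20.8 * pmax(rnorm(25, 25, 15), 0) / pmax(rnorm(25, 100, 20.8), 1)
    res <- exclude_outliers(v)
    expect_equal(res$is_excluded, oracle_outlier_flags(v))
    # partition preserves order and content
    expect_equal(c(res$retained, res$excluded),
                 c(v[!res$is_excluded], v[res$is_excluded]))
  }
})

test_that("summaries use the t quantile on n - 1 df", {
  s <- summarize_egl(c(5, 5, 5))
  expect_equal(s$mean, 5)
  expect_equal(s$ci_lo, 5)
  expect_equal(s$ci_hi, 5)

  # n = 24, SD 1.5: margin of error ~0.63 (reported as ~0.6)
  set.seed(1)
  v <- rnorm(24)
  v <- 4 + 1.5 * (v - mean(v)) / sd(v) # exact mean 4, SD 1.5
  s <- summarize_egl(v)
  expect_equal(s$sem, 1.5 / sqrt(24))
  expect_equal(s$ci_hi - s$mean, qt(0.975, 23) * 1.5 / sqrt(24))
  expect_equal(round(s$ci_hi - s$mean, 1), 0.6)

  # n = 25, SD 2.2: margin 2.0639 * 0.44
  v <- rnorm(25)
  v <- 5 + 2.2 * (v - mean(v)) / sd(v)
  s <- summarize_egl(v)
  expect_equal(s$sem, 0.44)
  expect_equal(s$ci_hi - s$mean, 0.908, tolerance = 1e-3)

  expect_error(summarize_egl(5), "at least 2")
})

test_that("CI width shrinks as 1/sqrt(n)", {
  widths <- sapply(c(10, 40, 160), function(n) {
    v <- seq(0, 1, length.out = n)
    v <- (v - mean(v)) / sd(v) * 2 + 5 # SD exactly 2
    s <- summarize_egl(v)
    s$ci_hi - s$ci_lo
  })
  expect_true(all(diff(widths) < 0))
  # ratio approaches 1/2 as the t quantile stabilises
  expect_equal(widths[3] / widths[2], 0.5, tolerance = 0.05)
})

test_that("pipeline recovers the dose when test equals reference", {
  tbl <- tibble::tibble(
    subject_id = "S01",
    meal_code = c("WB20.8#1", "WB20.8#2", "BAR"),
    analyte = "glucose",
    iauc = c(100, 100, 100)
  )
  res <- suppressWarnings(estimate_egl(tbl))
  expect_s3_class(res, "egl_result")
  expect_equal(res$subjects$egl, 20.8)
  expect_equal(res$subjects$reference_mean_iauc, 100)
})

test_that("pipeline averages two reference tests into W", {
  tbl <- tibble::tibble(
    subject_id = rep(c("S01", "S02"), each = 3),
    meal_code = rep(c("WB20.8#1", "WB20.8#2", "BAR"), 2),
    analyte = "glucose",
    iauc = c(90, 110, 50, 120, 80, 25)
  )
  res <- suppressWarnings(estimate_egl(tbl))
  expect_equal(sort(res$subjects$reference_mean_iauc), c(100, 100))
  expect_equal(sort(res$subjects$egl), 20.8 * c(25, 50) / 100)
})

test_that("pipeline flags an inflated subject as the excluded outlier", {
  set.seed(404)
  n <- 25
  w <- rep(100, n)
  t_iauc <- rnorm(n, 25, 3)
  t_iauc[7] <- 5 * 25
  tbl <- tibble::tibble(
    subject_id = rep(sprintf("S%02d", 1:n), 3),
    meal_code = rep(c("WB20.8#1", "WB20.8#2", "BAR"), each = n),
    analyte = "glucose",
    iauc = c(w, w, t_iauc)
  )
  res <- estimate_egl(tbl)
  excluded <- res$subjects$subject_id[res$subjects$excluded]
  expect_equal(excluded, "S07")
  expect_lt(res$summary$mean_retained, res$summary$mean_all)
})

test_that("pipeline errors without a reference meal and warns on gaps", {
  tbl <- tibble::tibble(
    subject_id = "S01", meal_code = "BAR", analyte = "glucose", iauc = 10
  )
  expect_error(estimate_egl(tbl), "reference meal")

  tbl2 <- tibble::tibble(
    subject_id = c("S01", "S02", "S03", "S01", "S02", "S03", "S01", "S02"),
    meal_code = c(rep("WB20.8#1", 3), rep("WB20.8#2", 3), "BAR", "BAR"),
    analyte = "glucose",
    iauc = c(100, 90, 110, 100, 110, 90, 40, 50)
  )
  # warns both about the subject missing the meal and the small group
  w <- capture_warnings(estimate_egl(tbl2))
  expect_true(any(grepl("S03", w)))
  expect_true(any(grepl("fewer than 3", w)))
})

test_that("EGL estimate is homogeneous in the test responses", {
  set.seed(505)
  n <- 12
  base <- tibble::tibble(
    subject_id = rep(sprintf("S%02d", 1:n), 3),
    meal_code = rep(c("WB20.8#1", "WB20.8#2", "BAR"), each = n),
    analyte = "glucose",
    iauc = c(rnorm(n, 100, 10), rnorm(n, 100, 10), rnorm(n, 30, 8))
  )
  res1 <- estimate_egl(base, exclude = FALSE)
  scaled <- base
  scaled$iauc[scaled$meal_code == "BAR"] <- 3 * scaled$iauc[scaled$meal_code == "BAR"]
  res3 <- estimate_egl(scaled, exclude = FALSE)
  expect_equal(res3$summary$mean_all, 3 * res1$summary$mean_all)
})

test_that("tidy and glance expose the per-meal and overall summaries", {
  tbl <- tibble::tibble(
    subject_id = rep(sprintf("S%02d", 1:5), 4),
    meal_code = rep(c("WB20.8#1", "WB20.8#2", "BAR", "CRISP"), each = 5),
    analyte = "glucose",
    iauc = c(rep(100, 10), rep(25, 5), rep(50, 5))
  )
  res <- estimate_egl(tbl)
  td <- tidy(res)
  expect_equal(nrow(td), 2)
  expect_true(all(td$ci_lo_retained <= td$mean_retained &
                    td$mean_retained <= td$ci_hi_retained))
  gl <- glance(res)
  expect_equal(gl$n_meals, 2)
  expect_equal(gl$n_subjects, 5)
})
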