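test_that("truncated normal draws clip negatives at exactly zero", {
  expect_equal(draw_truncated_normal(10, 25, 0), rep(25, 10))
  set.seed(11)
  v <- draw_truncated_normal(20000, 25, 15)
  expect_true(all(v >= 0))
  expect_equal(mean(v == 0), pnorm(-25 / 15), tolerance = 0.1)
  w <- draw_truncated_normal(3000, 100, 20.8, seed = 5)
  expect_lt(abs(mean(w) - 100), 3 * 20.8 / sqrt(3000))
  expect_error(draw_truncated_normal(0, 1, 1), "at least 1")
  expect_error(draw_truncated_normal(5, 1, -1), "non-negative")
})

test_that("degenerate simulation collapses to the deterministic ratio", {
  # constant draws make every normality check warn; that is the point here
  suppressWarnings(
    sim <- simulate_egl_population(
      n_subjects = 100, ref_sd = 0, test_sd = 0, group_size = 25, seed = 1
    )
  )
  expect_equal(sim$draws$egl, rep(20.8 * 25 / 100, 100))
  expect_equal(sim$n_excluded, 0)
  expect_equal(sim$sd_of_group_means_all, 0)
})

test_that("simulation is reproducible and internally consistent", {
  a <- simulate_egl_population(n_subjects = 500, group_size = 25, seed = 99)
  b <- simulate_egl_population(n_subjects = 500, group_size = 25, seed = 99)
  expect_identical(a$draws, b$draws)
  expect_identical(glance(a), glance(b))

  # counts add up
  expect_equal(a$n_excluded, a$n_excluded_above + a$n_excluded_below)
  expect_equal(a$n_excluded + length(a$draws$egl[!a$draws$excluded]),
               nrow(a$draws))
  expect_equal(sum(tidy(a)$n_excluded), a$n_excluded)

  # per-group flags match a brute-force recheck of each group's own rule
  for (g in unique(a$draws$group)) {
    v <- a$draws$egl[a$draws$group == g]
    expect_equal(a$draws$excluded[a$draws$group == g], oracle_outlier_flags(v))
  }
})

test_that("exclusion lowers the pooled mean of the right-skewed ratios", {
  for (s in 1:5) {
    sim <- simulate_egl_population(seed = s)
    expect_lt(sim$pooled_mean_retained, sim$pooled_mean_all)
    # outlier fraction in the 3%-6% window
    expect_gt(sim$n_excluded / 3000, 0.03)
    expect_lt(sim$n_excluded / 3000, 0.06)
    # group-mean SD tracks pooled SD / sqrt(group size)
    expect_equal(sim$sd_of_group_means_all,
                 sim$pooled_sd_all / sqrt(25), tolerance = 0.25)
  }
})

test_that("a trailing partial group is dropped with a warning", {
  expect_warning(
    sim <- simulate_egl_population(n_subjects = 60, group_size = 25, seed = 3),
    "trailing"
  )
  expect_equal(nrow(sim$draws), 50)
  expect_length(sim$group_means_all, 2)
  # the pooled pre-exclusion moments still use all 60 subjects
  expect_equal(sim$n_subjects, 60)
})

test_that("normality p-values behave qualitatively as expected", {
  set.seed(21)
  expect_warning(p <- normality_p(rep(3, 20)), "constant")
  expect_equal(p, 1)
  expect_error(normality_p(1:5), "at least 8")

  for (s in 1:3) {
    sim <- suppressWarnings(simulate_egl_population(seed = s))
    # the raw EGL ratios are decisively right-skewed ...
    expect_lt(sim$normality_p[["egl_all"]], 0.001)
    # ... exclusion moves the pooled sample toward normal ...
    expect_gt(sim$normality_p[["egl_retained"]], sim$normality_p[["egl_all"]])
    # ... the reference draws and the group means are consistent with normal
    expect_gt(sim$normality_p[["ref_draws"]], 0.01)
    expect_gt(normality_p(sim$group_means_all), 0.01)
  }

  # p-values are ~uniform under the null (fixed-seed KS check)
  ps <- replicate(200, shapiro.test(rnorm(500))$p.value)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)

  # large-sample fallback stays defined
  expect_gt(normality_p(rnorm(6000)), 0)
})

test_that("2x2 chi-square matches hand computation and edge cases", {
  res <- two_by_two_chi_square(10, 90, 10, 90)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  res <- two_by_two_chi_square(20, 80, 5, 95)
  expect_equal(res$statistic, 10.286, tolerance = 1e-3)
  expect_equal(res$p_value, 0.0013, tolerance = 0.05)

  expect_error(two_by_two_chi_square(0, 0, 5, 95), "total is zero")
  expect_error(two_by_two_chi_square(-1, 2, 3, 4), "non-negative")
})
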