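# Independent oracles used across the test files. These deliberately avoid
# the package's own code paths: the iAUC oracle integrates max(increment, 0)
# on a dense grid (with local refinement where the increment changes sign,
# so the clipped kink is resolved to ~1e-12), the outlier oracle re-applies
# the exclusion rule with naive arithmetic.

oracle_iauc <- function(time_min, concentration, fasting_times = c(-5, 0),
                        step = 0.001) {
  base <- mean(concentration[time_min %in% fasting_times])
  post <- time_min >= 0
  t <- time_min[post]
  y <- concentration[post] - base
  f <- function(s) approx(t, y, xout = s)$y
  grid <- seq(min(t), max(t), by = step)
  vals <- f(grid)
  v1 <- vals[-length(vals)]
  v2 <- vals[-1]
  cross <- which(v1 * v2 < 0)
  keep <- setdiff(seq_along(v1), cross)
  area <- sum((pmax(v1[keep], 0) + pmax(v2[keep], 0)) / 2) * step
  for (i in cross) {
    g <- seq(grid[i], grid[i + 1], length.out = 20001)
    fv <- pmax(f(g), 0)
    area <- area + sum((fv[-1] + fv[-length(fv)]) / 2) * (g[2] - g[1])
  }
  area
}

# Naive re-check of the single-pass exclusion rule.
oracle_outlier_flags <- function(values, z = 1.96) {
  m <- sum(values) / length(values)
  s <- sqrt(sum((values - m)^2) / (length(values) - 1))
  if (s == 0) rep(FALSE, length(values)) else abs(values - m) > z * s
}

# A random strictly-increasing sampling schedule with fasting samples.
random_curve <- function() {
  n_post <- sample(3:8, 1)
  times <- c(-5, 0, sort(sample(seq(5, 120, by = 5), n_post)))
  conc <- pmax(rnorm(length(times), mean = 6, sd = 1.5), 0)
  list(time_min = times, concentration = conc)
}
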