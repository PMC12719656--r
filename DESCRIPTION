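Package: eglr
Title: Equivalent Glycemic Load Estimation from Postprandial Glucose Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the glycemic impact of low-carbohydrate
    foods as equivalent glycemic load (EGL): incremental area under the
    curve (iAUC) for postprandial glucose and insulin time-courses using
    the trapezoid rule above the fasting baseline, per-subject and
    per-food EGL estimation with z-score outlier exclusion and
    t-distribution confidence intervals, Monte Carlo simulation of EGL
    values as scaled ratios of truncated normal responses, a synthetic
    crossover-cohort generator for end-to-end validation, and correlation
    of label macronutrient composition (available and net carbohydrate)
    with mean postprandial responses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    nortest,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
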