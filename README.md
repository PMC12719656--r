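# eglr

Equivalent glycemic load (EGL) estimation from postprandial glucose
responses, for nutrition researchers who need to quantify the glycemic
impact of low-carbohydrate foods.

## The problem

The glycemic index and glycemic load cannot be measured for low-carb
foods: a GI test requires subjects to eat ≥ 25 g of available carbohydrate
(avCHO) of the food in one sitting, which for such foods means implausibly
large portions. Worse, the Nutrition Facts Label overstates their glycemic
potential: label carbohydrate includes sweeteners such as allulose that are
absorbed but not metabolised, so *carbohydrate − fiber* (avCHO) is an upper
bound and even *avCHO − allulose* (netCHO) can overstate the realised
response when the food is rich in fat and protein.

EGL sidesteps the portion problem by asking: *how many grams of avCHO from
white bread elicit the same glucose response as one serving of the food?*
Each subject in a crossover trial eats the test food and a reference bread
portion containing a known dose `D` of avCHO (tested twice), and

```
EGL_i = D · T_i / W_i
```

where `T_i` is the subject's incremental area under the glucose curve
(iAUC) after the test food and `W_i` the mean iAUC of their two reference
tests. The iAUC is the trapezoid-rule area lying **above** the fasting
baseline (the mean of the −5 and 0 min samples), with segments clipped at
their baseline crossings. Because each `EGL_i` is a constant times a ratio
of two noisy responses, its distribution is right-skewed; per-food values
more than 1.96 SD from the mean are excluded in one pass, and the reported
EGL is the retained mean with a t-distribution 95% CI.

The package implements this chain end to end, plus:

* a **Monte Carlo simulation** of the EGL ratio distribution
  (`simulate_egl_population()`): reference ~ N(100, 20.8), test ~ N(25, 15),
  truncated at 0, screened for outliers in sequential groups of 25 — used to
  show how day-to-day variation skews the ratio and how exclusion
  de-biases it;
* a **synthetic cohort generator** (`generate_cohort()`) producing
  long-format finger-stick tables with lognormal between-subject and
  day-to-day variation and additive analytical noise, so the whole pipeline
  is testable against known truth;
* a **composition analysis** (`derive_carbs()`, `correlation_panel()`)
  relating label macronutrients (energy, fat, protein, avCHO, netCHO,
  %-energy shares, per-gram-netCHO ratios) to mean glucose/insulin iAUCs,
  with a packaged worked-example fixture.

## Worked example

```r
library(eglr)

cohort <- generate_cohort(cohort_config(
  n_subjects = 25,
  meals = data.frame(meal_code = c("WB5.2", "BAR"), true_egl = c(5.2, 2.0)),
  seed = 2024
))
estimate_egl(cohort)
#> Equivalent glycemic load (reference WB20.8, dose 20.8 g, outliers >1.96 SD excluded)
#>
#>   meal  n EGL (all) SEM excl. EGL (retained)     95% CI
#>    BAR 25       2.3 0.5     1            2.0 [1.2, 2.7]
#>  WB5.2 25       5.4 0.9     1            4.6 [3.4, 5.9]
```

The generator planted true EGLs of 5.2 g and 2.0 g. With realistic
day-to-day CVs (60% at low doses) the pre-exclusion means overshoot
(ratio skew), exclusion pulls them back, and the true values sit inside the
95% CIs. A low-dose bread portion recovering slightly *below* its nominal
dose after exclusion is exactly the behaviour the Monte Carlo model
predicts:

```r
simulate_egl_population(seed = 2024)
#> EGL Monte Carlo simulation (3000 subjects, groups of 25)
#>   reference draws: mean 100.3, SD 20.4
#>   test draws:      mean 25.3, SD 14.3
#>   EGL before exclusion: 5.50 +/- 3.50 g
#>   excluded: 114 (108 above, 6 below the group means)
#>   EGL after exclusion:  5.18 +/- 3.03 g
#>   SD of group means: 0.67 (all), 0.69 (retained)
```

The noise-free expectation is 20.8 × 25/100 = 5.2 g; ratio skew inflates
the raw mean to ~5.5 g, and ~4% of values are excluded, mostly above the
mean. `tidy()`, `glance()` and `autoplot()` methods are available for both
result types.

Composition vs response, on the packaged fixture (seven low-carb test
products; insulin panel excerpt):

```r
panel <- correlation_panel(
  dplyr::filter(meal_compositions(), !meal_code %in% c("WB20.8", "WB5.2")),
  dplyr::filter(mean_response_iaucs(), !grepl("^WB", meal_code))
)
#>                  x_name       y_name n     r     p
#>              protein_g insulin_iauc 7  0.69 0.087
#>     pct_energy_protein insulin_iauc 7  0.78 0.038
#>   protein_per_g_netcho insulin_iauc 7  0.86 0.014
#>                avcho_g insulin_iauc 7  0.32 0.480
```

Insulin responses track protein content; neither glucose nor insulin
responses correlate significantly with any carbohydrate measure in this
small panel.

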