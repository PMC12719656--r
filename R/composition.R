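#' Derive carbohydrate fractions and energy shares from label composition
#'
#' Adds to a per-serving composition table the derived fields used in the
#' nutritional-determinants analysis: available carbohydrate
#' `avcho_g = total_carb_g - fiber_g`, net carbohydrate
#' `netcho_g = avcho_g - allulose_g` (allulose is absorbed but not
#' metabolised, so it contributes label carbohydrate but no glycemic load),
#' percent of label energy from fat, protein and netCHO (9, 4 and 4 kcal/g),
#' and grams of fat and protein per gram of netCHO. Per-gram ratios are `NA`
#' when netCHO is zero.
#'
#' @param data Data frame with columns `meal_code`, `energy_kcal`, `fat_g`,
#'   `protein_g`, `total_carb_g`, `fiber_g`, `allulose_g` (missing
#'   `allulose_g` is taken as 0).
#' @return The input as a tibble with columns `avcho_g`, `netcho_g`,
#'   `pct_energy_fat`, `pct_energy_protein`, `pct_energy_netcho`,
#'   `fat_per_g_netcho`, `protein_per_g_netcho` appended.
#' @examples
#' derive_carbs(data.frame(
#'   meal_code = "PBCer", energy_kcal = 247, fat_g = 11, protein_g = 34,
#'   total_carb_g = 14, fiber_g = 2, allulose_g = 6
#' ))
#' @export
derive_carbs <- function(data) {
  required <- c("meal_code", "energy_kcal", "fat_g", "protein_g",
                "total_carb_g", "fiber_g")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  data <- as_tibble(data)
  if (!"allulose_g" %in% names(data)) data$allulose_g <- 0
  if (any(data$fiber_g > data$total_carb_g)) {
    abort("fiber_g exceeds total_carb_g")
  }
  out <- data |>
    mutate(
      avcho_g = .data$total_carb_g - .data$fiber_g,
      netcho_g = .data$avcho_g - .data$allulose_g,
      pct_energy_fat = 100 * 9 * .data$fat_g / .data$energy_kcal,
      pct_energy_protein = 100 * 4 * .data$protein_g / .data$energy_kcal,
      pct_energy_netcho = 100 * 4 * .data$netcho_g / .data$energy_kcal,
      fat_per_g_netcho = ifelse(.data$netcho_g > 0,
                                .data$fat_g / .data$netcho_g, NA_real_),
      protein_per_g_netcho = ifelse(.data$netcho_g > 0,
                                    .data$protein_g / .data$netcho_g, NA_real_)
    )
  if (any(out$netcho_g < 0)) {
    abort("negative netCHO: allulose_g exceeds available carbohydrate")
  }
  out
}

#' Pearson correlation with a t-test p-value
#'
#' Sample Pearson correlation between two vectors with the two-sided p-value
#' from the t transform on n - 2 degrees of freedom (via [stats::cor.test()]).
#'
#' @param x,y Numeric vectors of equal length, n >= 3, neither constant.
#' @return A one-row tibble: `n`, `r`, `p`.
#' @examples
#' pearson_r(c(1, 2, 3), c(6, 4, 5)) # r = -0.5
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have the same length")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) abort("constant input; correlation undefined")
  ct <- cor.test(x, y, method = "pearson")
  tibble(n = length(x), r = unname(ct$estimate), p = ct$p.value)
}

#' Correlation panel of composition measures against mean responses
#'
#' Correlates each composition measure (energy, fat, protein, total
#' carbohydrate, avCHO, netCHO, the percent-energy shares, and the per-gram
#' netCHO ratios) with the mean glucose and insulin iAUC per meal, plus the
#' glucose-vs-insulin pair. Pairs whose correlation is undefined (constant or
#' too few values) are reported with `NA` and the panel continues.
#'
#' @param compositions Composition table (see [derive_carbs()]; derived
#'   columns are added if absent).
#' @param mean_iaucs Data frame with `meal_code`, `glucose_iauc` and
#'   optionally `insulin_iauc`, one row per meal (mean responses).
#' @return A tibble with `x_name`, `y_name`, `n`, `r`, `p`, one row per pair.
#' @examples
#' correlation_panel(meal_compositions()[-(1:2), ], mean_response_iaucs()[-(1:3), ])
#' @export
correlation_panel <- function(compositions, mean_iaucs) {
  if (!"avcho_g" %in% names(compositions)) {
    compositions <- derive_carbs(compositions)
  }
  joined <- inner_join(as_tibble(compositions), as_tibble(mean_iaucs),
                       by = "meal_code")
  if (nrow(joined) < 3) abort("need at least 3 meals with composition and response")

  predictors <- c(
    "energy_kcal", "fat_g", "protein_g", "total_carb_g", "avcho_g",
    "netcho_g", "pct_energy_fat", "pct_energy_protein", "pct_energy_netcho",
    "fat_per_g_netcho", "protein_per_g_netcho"
  )
  responses <- intersect(c("glucose_iauc", "insulin_iauc"), names(joined))

  pairs <- expand.grid(x_name = predictors, y_name = responses,
                       stringsAsFactors = FALSE)
  if (all(c("glucose_iauc", "insulin_iauc") %in% responses)) {
    pairs <- rbind(pairs,
                   data.frame(x_name = "glucose_iauc", y_name = "insulin_iauc"))
  }
  purrr::pmap(pairs, function(x_name, y_name) {
    res <- tryCatch(
      pearson_r(joined[[x_name]], joined[[y_name]]),
      error = function(e) {
        warn(paste0(x_name, " vs ", y_name, ": ", conditionMessage(e)))
        tibble(n = NA_integer_, r = NA_real_, p = NA_real_)
      }
    )
    tibble(x_name = x_name, y_name = y_name, res)
  }) |>
    list_rbind()
}

#' Packaged per-serving composition of the worked-example meals
#'
#' Label composition (per serving) of the two white-bread reference portions
#' and seven commercial-style low-carbohydrate test products from a 25-adult
#' crossover study, with derived carbohydrate fractions. Five of the products
#' are sweetened with allulose.
#'
#' @return A tibble, one row per meal (see [derive_carbs()] for columns).
#' @examples
#' meal_compositions()
#' @export
meal_compositions <- function() {
  path <- system.file("extdata", "meal_composition.csv", package = "eglr",
                      mustWork = TRUE)
  derive_carbs(read_composition(path))
}

#' Packaged mean postprandial iAUC responses of the worked-example meals
#'
#' Mean glucose (mmol x min/L) and insulin (pmol x h/L) iAUCs in the 10
#' subjects of the same crossover study in whom both analytes were measured.
#'
#' @return A tibble: `meal_code`, `glucose_iauc`, `insulin_iauc`, `n_subjects`.
#' @examples
#' mean_response_iaucs()
#' @export
mean_response_iaucs <- function() {
  path <- system.file("extdata", "mean_iauc.csv", package = "eglr",
                      mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE)
}
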