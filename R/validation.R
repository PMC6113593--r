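# Validation of calculated nutrient values against chemical reference
# measurements using mean absolute percentage deviation (MAPD).
#
# Per nutrient, MAPD = |calculated - measured| / measured * 100. The
# measured value is the reference, so MAPD is deliberately asymmetric in
# (calculated, measured). A zero measured value leaves the cell undefined
# (NA, displayed as an em dash) — a relative deviation from zero has no
# scale. A zero calculated value against a positive measurement is a 100%
# deviation.

#' Mean absolute percentage deviation
#'
#' Vectorized MAPD core: `|calculated - measured| / measured * 100`, with
#' `NA` (undefined) exactly where `measured == 0`. Scale-invariant:
#' `mapd(k * c, k * m)` equals `mapd(c, m)` for any `k > 0`.
#'
#' @param calculated Numeric vector of calculated values.
#' @param measured Numeric vector of reference (measured) values, `>= 0`.
#' @return Numeric vector of percentage deviations (full precision; use
#'   [round_half_up()] with 2 digits for display).
#' @export
#' @examples
#' mapd(288.1, 253) # 13.87 at 2 decimals
#' mapd(0, 0.8)     # 100
#' mapd(0, 0)       # NA: undefined
mapd <- function(calculated, measured) {
  if (any(measured < 0, na.rm = TRUE)) {
    abort("measured reference values must be >= 0",
          class = "dietledger_validation_error")
  }
  ifelse(measured == 0, NA_real_, abs(calculated - measured) / measured * 100)
}

#' Read a reference-measurement file
#'
#' CSV with columns `dish`, `nutrient`, `measured_per_100g` and `method`
#' (free-text assay annotation, e.g. Kjeldahl nitrogen for protein, acid
#' hydrolysis for fat).
#'
#' @param path Path to the reference CSV.
#' @return Tibble of class `reference_measurements`.
#' @export
read_reference_measurements <- function(path) {
  x <- readr::read_csv(
    path,
    col_types = readr::cols(
      dish = readr::col_character(),
      nutrient = readr::col_character(),
      measured_per_100g = readr::col_double(),
      method = readr::col_character()
    ),
    progress = FALSE
  )
  x$dish <- normalize_food_name(x$dish)
  if (any(x$measured_per_100g < 0, na.rm = TRUE)) {
    abort("measured values must be >= 0", class = "dietledger_validation_error")
  }
  structure(x, class = unique(c("reference_measurements", class(x))))
}

#' Deviation report: calculated vs measured nutrient values
#'
#' Joins per-dish calculated and measured nutrient values and computes the
#' per-nutrient MAPD. Only nutrients present in both inputs are compared;
#' no shared nutrient for a dish raises an empty-comparison error.
#'
#' @param calculated Long tibble with columns `dish`, `nutrient`,
#'   `calculated_per_100g` (see [pivot_nutrients_long()] to convert the
#'   wide output of [dish_nutrient_table()]).
#' @param reference Long tibble with columns `dish`, `nutrient`,
#'   `measured_per_100g` (a `reference_measurements` object).
#' @return Tibble of class `deviation_report` with one row per shared
#'   (dish, nutrient): `dish`, `nutrient`, `calculated`, `measured`,
#'   `mapd` (full precision, `NA` when undefined) and `mapd_display`
#'   (2-decimal half-up rounding, `"—"` when undefined).
#' @export
deviation_report <- function(calculated, reference) {
  calc <- as_tibble(calculated)
  ref <- as_tibble(reference)[c("dish", "nutrient", "measured_per_100g")]
  calc$dish <- normalize_food_name(calc$dish)
  ref$dish <- normalize_food_name(ref$dish)
  joined <- dplyr::inner_join(calc, ref, by = c("dish", "nutrient"))
  if (nrow(joined) == 0) {
    abort("no shared (dish, nutrient) pairs between calculation and reference",
          class = "dietledger_empty_comparison_error")
  }
  dev <- mapd(joined$calculated_per_100g, joined$measured_per_100g)
  out <- tibble(
    dish = joined$dish,
    nutrient = joined$nutrient,
    calculated = joined$calculated_per_100g,
    measured = joined$measured_per_100g,
    mapd = dev,
    mapd_display = ifelse(is.na(dev),
                          "—",
                          sprintf("%.2f", round_half_up(dev, 2)))
  )
  structure(out, class = unique(c("deviation_report", class(out))))
}

#' Validate calculated nutrient values against reference measurements
#'
#' Two modes. In replication mode, pass `calculated` directly (long tibble
#' of printed calculated values) and the report reproduces the published
#' comparison exactly. In computed mode, leave `calculated = NULL` and
#' supply `recipes` and `table`: each reference dish's nutrient content is
#' computed from its recipe with [nutrient_content_per_100g()] (a
#' reference dish absent from the recipe database raises a lookup error).
#'
#' @param reference A `reference_measurements` tibble.
#' @param calculated Optional long tibble (`dish`, `nutrient`,
#'   `calculated_per_100g`); replication mode when supplied.
#' @param recipes,table Recipe database and composition table for computed
#'   mode.
#' @param include_auxiliary Passed to the engine in computed mode.
#' @return A `deviation_report` covering every reference dish.
#' @export
validate_against_reference <- function(reference, calculated = NULL,
                                       recipes = NULL, table = NULL,
                                       include_auxiliary = FALSE) {
  if (is.null(calculated)) {
    if (is.null(recipes) || is.null(table)) {
      abort("computed mode needs both `recipes` and `table`",
            class = "dietledger_validation_error")
    }
    dishes <- unique(normalize_food_name(reference$dish))
    wide <- bind_rows(purrr::map(dishes, function(d) {
      suppressWarnings(
        nutrient_content_per_100g(get_recipe(recipes, d), table,
                                  include_auxiliary)
      )
    }))
    calculated <- pivot_nutrients_long(wide)
  }
  deviation_report(calculated, reference)
}

#' Pivot a wide per-100 g nutrient table to long comparison form
#'
#' @param wide Tibble with a `dish` column and nutrient columns (output of
#'   [dish_nutrient_table()] or [nutrient_content_per_100g()]).
#' @param values_to Name for the value column; default
#'   `"calculated_per_100g"`.
#' @return Long tibble: `dish`, `nutrient`, value column.
#' @export
pivot_nutrients_long <- function(wide, values_to = "calculated_per_100g") {
  tidyr::pivot_longer(as_tibble(wide), -"dish",
                      names_to = "nutrient", values_to = values_to)
}

#' Per-dish mean of defined MAPD cells
#'
#' Optional dish-level summary: the mean of a dish's defined (non-`NA`)
#' per-nutrient MAPD values. The per-nutrient cells in
#' [deviation_report()] are the primary output; this summary is a
#' convenience.
#'
#' @param report A `deviation_report`.
#' @return Tibble: `dish`, `n_defined`, `mean_mapd`.
#' @export
dish_mean_mapd <- function(report) {
  as_tibble(report) |>
    group_by(.data$dish) |>
    summarise(
      n_defined = sum(!is.na(.data$mapd)),
      mean_mapd = mean(.data$mapd, na.rm = TRUE),
      .groups = "drop"
    )
}
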