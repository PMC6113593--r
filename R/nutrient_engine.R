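# Nutrient engine: dish -> ingredients -> nutrients.
#
# A dish of total weight W is decomposed by scaling each counted recipe
# ingredient in proportion to its raw weight, so scaled weights sum to W.
# Per-100 g nutrient content is the weight-fraction-weighted sum of the
# ingredients' per-100 g values, on a raw-weight basis: no cooking yield or
# retention correction is applied. Nutrient cells that are absent ("not
# measured") for any contributing ingredient stay absent (NA) in the sum
# rather than being coerced to zero, so intake is never silently
# understated.

#' Decompose a dish into scaled ingredient weights
#'
#' Splits a serving of `serving_weight_g` grams across the recipe's
#' ingredients in proportion to their raw recipe weights. Auxiliary
#' (condiment-scale) ingredients are excluded from the decomposition and
#' from the proportion denominator unless `include_auxiliary = TRUE`.
#' Output weights always sum to `serving_weight_g` (mass conservation).
#'
#' @param recipe One-row `recipe_db` slice (see [get_recipe()]).
#' @param serving_weight_g Serving weight in grams; must be positive.
#' @param include_auxiliary Count auxiliary ingredients? Default `FALSE`.
#' @return Tibble with columns `ingredient` and `weight_g`, sorted by
#'   ingredient name for reproducible downstream accumulation order.
#' @export
#' @examples
#' db <- as_recipe_db(tibble::tibble(
#'   dish = "demo", dish_type = "cooked", method = "stir-fry",
#'   ingredients = list(tibble::tibble(
#'     ingredient = c("a", "b"), weight_g = c(300, 100), auxiliary = FALSE))
#' ))
#' decompose_dish(get_recipe(db, "demo"), 200)
decompose_dish <- function(recipe, serving_weight_g, include_auxiliary = FALSE) {
  if (!is_scalar_number(serving_weight_g) || serving_weight_g <= 0) {
    abort("serving_weight_g must be a single positive number",
          class = "dietledger_validation_error")
  }
  ing <- recipe$ingredients[[1]]
  if (!include_auxiliary) ing <- ing[!ing$auxiliary, , drop = FALSE]
  total <- sum(ing$weight_g)
  if (nrow(ing) == 0 || total <= 0) {
    abort(paste0("recipe '", recipe$dish, "' has zero counted weight"),
          class = "dietledger_degenerate_recipe_error")
  }
  out <- tibble(
    ingredient = ing$ingredient,
    weight_g = ing$weight_g / total * serving_weight_g
  )
  arrange(out, .data$ingredient)
}

#' Nutrient content of a dish per 100 g
#'
#' Computes the nutrient vector of 100 g of a dish as the weighted sum of
#' its ingredients' per-100 g values: for nutrient x,
#' `c_x = sum_i (w_i / 100) * n_xi`, where `w_i` are the scaled ingredient
#' weights of a 100 g serving (from [decompose_dish()]) and `n_xi` the
#' ingredient's amount per 100 g from the composition table.
#'
#' A nutrient that is absent (`NA`) for any contributing ingredient is
#' absent in the result, with the affected nutrients listed in the
#' `absent_nutrients` attribute and raised as a warning.
#'
#' @param recipe One-row `recipe_db` slice.
#' @param table A `food_composition` tibble covering the recipe's counted
#'   ingredients (else a lookup error naming the first missing ingredient).
#' @param include_auxiliary Count auxiliary ingredients? Default `FALSE`.
#' @return One-row tibble with `dish` plus one column per nutrient in the
#'   table, amounts per 100 g of dish.
#' @export
nutrient_content_per_100g <- function(recipe, table, include_auxiliary = FALSE) {
  missing <- validate_recipe_coverage(recipe, table, include_auxiliary)
  if (length(missing) > 0) {
    abort(paste0("recipe '", recipe$dish,
                 "' has ingredient(s) not in composition table: ",
                 paste(missing, collapse = ", ")),
          class = "dietledger_lookup_error")
  }
  parts <- decompose_dish(recipe, 100, include_auxiliary)
  nutrients <- composition_nutrients(table)
  comp <- as_tibble(table)[c("ingredient", nutrients)]
  joined <- left_join(parts, comp, by = "ingredient")

  frac <- joined$weight_g / 100
  vals <- vapply(nutrients, function(nu) sum(frac * joined[[nu]]), numeric(1))
  absent <- nutrients[is.na(vals)]
  if (length(absent) > 0) {
    warn(paste0("dish '", recipe$dish, "': nutrient(s) absent for some ",
                "ingredient, result marked absent: ",
                paste(absent, collapse = ", ")))
  }
  out <- as_tibble(c(list(dish = recipe$dish), as.list(vals)))
  structure(out, absent_nutrients = absent)
}

#' Per-100 g nutrient content for every dish in a recipe database
#'
#' Vectorized companion of [nutrient_content_per_100g()]; uncovered dishes
#' are skipped with a warning rather than erroring, so it can be run on a
#' database before filtering.
#'
#' @param recipes A `recipe_db` tibble.
#' @param table A `food_composition` tibble.
#' @param include_auxiliary Count auxiliary ingredients? Default `FALSE`.
#' @return Tibble: one row per covered dish, columns `dish` + nutrients.
#' @export
dish_nutrient_table <- function(recipes, table, include_auxiliary = FALSE) {
  cov <- coverage_report(recipes, table, include_auxiliary)
  if (any(!cov$covered)) {
    warn(paste0("skipping ", sum(!cov$covered),
                " dish(es) not covered by the composition table"))
  }
  rows <- purrr::map(which(cov$covered), function(i) {
    suppressWarnings(
      nutrient_content_per_100g(recipes[i, ], table, include_auxiliary)
    )
  })
  bind_rows(rows)
}

#' Per-serving nutrient intake for one plate event
#'
#' Scales the dish's per-100 g nutrient vector to the serving:
#' `amount = per_100g * serving_weight_g / 100`, exactly linear in serving
#' weight.
#'
#' @param event One-row `plate_events` slice that survived selection.
#' @param recipes A `recipe_db` tibble.
#' @param table A `food_composition` tibble.
#' @param include_auxiliary Count auxiliary ingredients? Default `FALSE`.
#' @return One-row intake tibble: `consumer_id`, `date`, `dish_name`,
#'   `serving_weight_g`, then absolute nutrient amounts for the serving.
#' @export
intake_for_event <- function(event, recipes, table, include_auxiliary = FALSE) {
  intake_records(event, recipes, table, include_auxiliary)
}

#' Per-serving nutrient intake for a stream of plate events
#'
#' Computes each unique dish's per-100 g vector once, then scales it to
#' every event's serving weight. Lookup errors propagate: every event must
#' reference a covered recipe (run [apply_selection_filters()] first).
#'
#' @param events A `plate_events` tibble (post-selection).
#' @param recipes A `recipe_db` tibble.
#' @param table A `food_composition` tibble.
#' @param include_auxiliary Count auxiliary ingredients? Default `FALSE`.
#' @return Tibble of class `intake_records`, one row per event in input
#'   order: `consumer_id`, `date`, `dish_name`, `serving_weight_g`, plus
#'   one absolute-amount column per nutrient.
#' @export
intake_records <- function(events, recipes, table, include_auxiliary = FALSE) {
  x <- as_tibble(events)
  nutrients <- composition_nutrients(table)
  dishes <- unique(x$dish_name)
  per100 <- bind_rows(purrr::map(dishes, function(d) {
    suppressWarnings(
      nutrient_content_per_100g(get_recipe(recipes, d), table, include_auxiliary)
    )
  }))
  out <- x[c("consumer_id", "date", "dish_name", "serving_weight_g")]
  out <- left_join(out, rename(per100, dish_name = "dish"), by = "dish_name")
  for (nu in nutrients) out[[nu]] <- out[[nu]] * out$serving_weight_g / 100
  structure(out, nutrients = nutrients,
            class = c("intake_records", class(out)))
}

#' Aggregate intake records
#'
#' Grouped component-wise sums of absolute nutrient amounts. An absent
#' (`NA`) summand makes the group's nutrient absent, with a warning — never
#' silently coerced to zero.
#'
#' @param records An `intake_records` tibble.
#' @param by Grouping: `"consumer"` (total per consumer),
#'   `"consumer_date"` (daily series per consumer — the individual-level
#'   output), or `"population_date"` (daily population totals).
#' @return Tibble of class `intake_series` with the grouping columns,
#'   `n_events`, and summed nutrient columns; for date groupings, rows are
#'   ordered by strictly increasing date within group.
#' @export
aggregate_intake <- function(records,
                             by = c("consumer_date", "consumer", "population_date")) {
  by <- match.arg(by)
  nutrients <- attr(records, "nutrients") %||% setdiff(
    names(records), c("consumer_id", "date", "dish_name", "serving_weight_g")
  )
  keys <- switch(by,
    consumer = "consumer_id",
    consumer_date = c("consumer_id", "date"),
    population_date = "date"
  )
  out <- as_tibble(records) |>
    group_by(across(all_of(keys))) |>
    summarise(
      n_events = n(),
      across(all_of(nutrients), sum),
      .groups = "drop"
    ) |>
    arrange(across(all_of(keys)))
  dropped <- nutrients[vapply(out[nutrients], anyNA, logical(1))]
  if (length(dropped) > 0) {
    warn(paste0("absent nutrient values propagated into aggregate(s): ",
                paste(dropped, collapse = ", ")))
  }
  structure(out, nutrients = nutrients, by = by,
            class = unique(c("intake_series", class(out))))
}
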