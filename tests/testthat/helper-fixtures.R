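# Shared in-code fixtures: a small composition table and recipe database
# with hand-checkable values, plus independent oracles used to cross-check
# the engine and the report tallies.

tiny_composition <- function() {
  as_composition_table(tibble::tibble(
    ingredient = c("rice", "tomato", "egg", "cabbage", "pork", "tofu"),
    category = c("cereals",
                 "vegetables and vegetable products",
                 "eggs",
                 "vegetables and vegetable products",
                 "meat and meat products",
                 "legumes"),
    energy_kcal = c(346, 20, 144, 24, 395, 82),
    protein_g = c(7.4, 0.9, 13.3, 1.5, 13.2, 8.1),
    fat_g = c(0.8, 0.2, 8.8, 0.2, 37, 3.7),
    carbohydrate_g = c(77.9, 4, 2.8, 4.7, 2.4, 4.2),
    fiber_g = c(0.7, 0.5, 0, 0.8, 0, 0.4)
  ), source = "test fixture")
}

tiny_recipes <- function() {
  ing <- function(ingredient, weight_g, auxiliary = FALSE) {
    tibble::tibble(ingredient = ingredient, weight_g = weight_g,
                   auxiliary = auxiliary)
  }
  as_recipe_db(tibble::tibble(
    dish = c("plain rice", "tomato egg", "braised pork", "tofu soup"),
    dish_type = c("staple", "cooked", "cooked", "porridge_soup"),
    method = c("steam", "stir-fry", "braise", "boil"),
    ingredients = list(
      ing("rice", 150),
      ing(c("tomato", "egg", "scallion"), c(200, 100, 5),
          c(FALSE, FALSE, TRUE)),
      ing(c("pork", "cabbage"), c(250, 150)),
      ing(c("tofu", "cabbage"), c(120, 80))
    )
  ), source = "test fixture")
}

tiny_events <- function() {
  tibble::tibble(
    consumer_id = rep("C1", 4),
    dish_name = c("plain rice", "tomato egg", "braised pork", "tofu soup"),
    plate_type = c(1L, 2L, 2L, 3L),
    serving_weight_g = c(200, 250, 300, 250),
    price = c(2, 6, 9, 3),
    meal_slot = "lunch",
    date = as.Date("2016-01-05") + 0:3
  )
}

# Independent brute-force oracle for per-100 g nutrient content: explicit
# loops and per-ingredient lookups, sharing no code with the engine.
oracle_per100g <- function(recipe_row, composition, include_auxiliary = FALSE) {
  ing <- recipe_row$ingredients[[1]]
  comp <- as.data.frame(composition)
  nutrients <- setdiff(names(comp), c("ingredient", "category"))
  total <- 0
  for (i in seq_len(nrow(ing))) {
    if (include_auxiliary || !ing$auxiliary[i]) total <- total + ing$weight_g[i]
  }
  out <- stats::setNames(rep(0, length(nutrients)), nutrients)
  for (i in seq_len(nrow(ing))) {
    if (!include_auxiliary && ing$auxiliary[i]) next
    scaled <- ing$weight_g[i] / total * 100
    row <- comp[comp$ingredient == ing$ingredient[i], ]
    for (nu in nutrients) {
      out[nu] <- out[nu] + scaled / 100 * row[[nu]]
    }
  }
  out
}

# data.frame comparison stripped of everything but the tabular content
plain_df <- function(x) {
  x <- as.data.frame(x)
  attributes(x) <- attributes(x)[c("names", "row.names", "class")]
  rownames(x) <- NULL
  x
}

# Independent tally oracle for distribution reports.
oracle_tally <- function(labels) {
  tab <- sort(table(labels), decreasing = TRUE)
  data.frame(label = names(tab), count = as.integer(tab))
}
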