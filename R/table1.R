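# Published benchmark: calculated vs chemically measured nutrient content
# of three Chinese dishes (garlic puree cooked pork leg, dry-fried string
# beans, roast lamb). Protein was measured by the Kjeldahl nitrogen method
# and fat by acid hydrolysis. Values are per 100 g of dish.

#' Calculated/measured nutrient benchmark for three Chinese dishes
#'
#' Returns the published comparison fixture: calculated nutrient content
#' and chemical reference measurements (energy, protein, fat, carbohydrate
#' per 100 g) for garlic puree cooked pork leg (steamed), dry-fried string
#' beans (stir-fried) and roast lamb (roasted). The same values ship as
#' plain CSVs under `inst/extdata/` (`table1_calculated.csv`,
#' `table1_reference.csv`).
#'
#' @return List with `calculated` (long tibble: `dish`, `nutrient`,
#'   `calculated_per_100g`) and `reference` (a `reference_measurements`
#'   tibble: `dish`, `nutrient`, `measured_per_100g`, `method`).
#' @export
#' @examples
#' fx <- make_table1_fixture()
#' validate_against_reference(fx$reference, calculated = fx$calculated)
make_table1_fixture <- function() {
  dishes <- c("garlic puree cooked pork leg", "dry-fried string beans",
              "roast lamb")
  nutrients <- c("energy_kcal", "protein_g", "fat_g", "carbohydrate_g")
  calc <- c(
    288.1, 25, 20.9, 0,      # pork leg
    210.7, 9.25, 18.2, 5.73, # string beans
    133.4, 19.4, 6.2, 0      # roast lamb
  )
  meas <- c(
    253, 22, 18.3, 0,
    229, 10.8, 16.7, 9,
    162, 21.5, 8.1, 0.8
  )
  method <- rep(c("bomb calorimetry", "Kjeldahl nitrogen",
                  "acid hydrolysis", "difference method"), times = 3)
  base <- tibble(
    dish = rep(dishes, each = 4),
    nutrient = rep(nutrients, times = 3)
  )
  calculated <- mutate(base, calculated_per_100g = calc)
  reference <- structure(
    mutate(base, measured_per_100g = meas, method = method),
    class = c("reference_measurements", "tbl_df", "tbl", "data.frame")
  )
  list(calculated = calculated, reference = reference)
}

#' Recipes of the three benchmark dishes
#'
#' The published comparison names the dishes' ingredients and preparation
#' methods but not the ingredient weights; the weights here are synthetic
#' placeholders so the recipes validate structurally. Condiment-scale
#' ingredients (garlic, scallions, pepper, dried chilies, cumin) carry the
#' auxiliary flag.
#'
#' @return A `recipe_db` with the three dishes.
#' @export
table1_recipes <- function() {
  mk <- function(ing, w, aux) tibble(ingredient = ing, weight_g = w, auxiliary = aux)
  as_recipe_db(tibble(
    dish = c("garlic puree cooked pork leg", "dry-fried string beans",
             "roast lamb"),
    dish_type = c("cooked", "cooked", "cooked"),
    method = c("steam", "stir-fry", "roast"),
    ingredients = list(
      mk(c("pork leg", "garlic", "scallions", "pepper"),
         c(500, 20, 10, 2), c(FALSE, TRUE, TRUE, TRUE)),
      mk(c("string beans", "minced pork", "dried chilies", "garlic", "scallions"),
         c(400, 80, 5, 10, 10), c(FALSE, FALSE, TRUE, TRUE, TRUE)),
      mk(c("lamb", "onion", "cumin", "vegetable oil"),
         c(450, 100, 5, 30), c(FALSE, FALSE, TRUE, FALSE))
    )
  ), source = "synthetic benchmark recipes")
}
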