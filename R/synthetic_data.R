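# Seeded simulator: synthetic menus, composition tables and multi-week
# plate-event streams emulating a workplace restaurant where every consumer
# has stable dish preferences. Every generator is a pure function of
# (config, seed): the same config yields byte-identical output.
#
# Deliberate corruptions mirror the four selection-filter stages (wrong
# meal slot, bad plate type, unknown dish, uncovered ingredient) so filter
# tests have planted ground truth.

#' Simulation configuration
#'
#' Builds the configuration object consumed by the generators. Defaults
#' describe a mid-sized workplace restaurant observed over six working
#' weeks: 50 consumers, a 50-dish menu split roughly 16/80/4% across
#' staple, cooked and porridge/soup dishes (mirroring a typical Chinese
#' lunch menu composition), two plates per consumer per lunch, and
#' plate-type serving ranges of 100-250 g (staple), 150-300 g (cooked) and
#' 200-400 g (soup).
#'
#' @param n_consumers Number of consumers.
#' @param start_date First calendar date emitted (ISO string or Date).
#' @param n_days Number of days to emit, counted after the
#'   `working_days_only` restriction.
#' @param working_days_only Emit Monday-Friday only? Default `TRUE`.
#' @param meal_slots Meal slots to emit. Default lunch only.
#' @param menu_size Named integer vector: dishes per dish type.
#' @param n_ingredients Size of the ingredient pool the menu draws from.
#' @param n_nutrients Number of nutrient columns in the composition table
#'   (5 core + up to 18 further nutrients; max 23).
#' @param missing_rate Fraction of non-core nutrient cells left absent
#'   (`NA`, "not measured") in the composition table.
#' @param plates_per_meal Plates drawn per consumer per slot per day.
#' @param serving_weight_range Named list of `c(min, max)` gram ranges per
#'   dish type.
#' @param preference_concentration Dirichlet concentration of per-consumer
#'   preference weights over the menu; smaller = more idiosyncratic.
#' @param corruption_rate Fraction of event rows to corrupt (one planted
#'   violation per corrupted row, cycling over the four filter stages).
#' @param n_uncovered_dishes Dishes planted in the recipe database with an
#'   ingredient deliberately missing from the composition table (needed
#'   when corruptions include the uncovered-ingredient kind).
#' @param seed Integer seed; all generators derive their streams from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_consumers = 50,
                       start_date = "2016-01-05",
                       n_days = 30,
                       working_days_only = TRUE,
                       meal_slots = "lunch",
                       menu_size = c(staple = 8, cooked = 40, porridge_soup = 2),
                       n_ingredients = 60,
                       n_nutrients = 23,
                       missing_rate = 0.05,
                       plates_per_meal = 2,
                       serving_weight_range = list(staple = c(100, 250),
                                                   cooked = c(150, 300),
                                                   porridge_soup = c(200, 400)),
                       preference_concentration = 1,
                       corruption_rate = 0,
                       n_uncovered_dishes = 0,
                       seed = 1) {
  stopifnot(
    n_consumers >= 1, n_days >= 1,
    all(meal_slots %in% meal_slots()),
    all(names(menu_size) %in% dish_types()), all(menu_size >= 0),
    sum(menu_size) >= 1,
    n_nutrients >= 5, n_nutrients <= 23,
    missing_rate >= 0, missing_rate < 1,
    plates_per_meal >= 1,
    corruption_rate >= 0, corruption_rate < 1,
    all(vapply(serving_weight_range, function(r) length(r) == 2 && all(r > 0),
               logical(1)))
  )
  structure(
    list(
      n_consumers = as.integer(n_consumers),
      start_date = as.Date(start_date),
      n_days = as.integer(n_days),
      working_days_only = isTRUE(working_days_only),
      meal_slots = meal_slots,
      menu_size = menu_size,
      n_ingredients = as.integer(n_ingredients),
      n_nutrients = as.integer(n_nutrients),
      missing_rate = missing_rate,
      plates_per_meal = as.integer(plates_per_meal),
      serving_weight_range = serving_weight_range,
      preference_concentration = preference_concentration,
      corruption_rate = corruption_rate,
      n_uncovered_dishes = as.integer(n_uncovered_dishes),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# run fn with a locally seeded RNG stream, restoring global state after
with_sim_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

extra_nutrient_names <- function() {
  c("calcium_mg", "iron_mg", "zinc_mg", "vitamin_a_ug", "vitamin_b1_mg",
    "vitamin_b2_mg", "vitamin_c_mg", "vitamin_e_mg", "niacin_mg",
    "cholesterol_mg", "magnesium_mg", "phosphorus_mg", "potassium_mg",
    "sodium_mg", "selenium_ug", "copper_mg", "manganese_mg", "carotene_ug")
}

#' Generate a synthetic recipe database and composition table
#'
#' Draws an ingredient pool with food-group categories and plausible
#' per-100 g nutrient values, then builds a menu of recipes per dish type:
#' staple dishes from cereals/tubers, cooked dishes mixing a protein source
#' with vegetables, porridge/soup dishes from light ingredients, each with
#' a chance of condiment-scale auxiliary ingredients (ginger, garlic,
#' scallion). Every recipe is fully covered by the generated composition
#' table, except the `n_uncovered_dishes` planted dishes, which reference
#' one ingredient deliberately absent from the table (their names are
#' recorded in the `uncovered_dishes` attribute of the returned recipe
#' database).
#'
#' @param config A [sim_config()].
#' @return List with `recipes` (a `recipe_db`) and `composition` (a
#'   `food_composition`).
#' @export
generate_food_knowledge <- function(config) {
  with_sim_seed(config$seed, function() generate_food_knowledge_impl(config))
}

generate_food_knowledge_impl <- function(config) {
  n_ing <- config$n_ingredients
  cats <- food_categories()
  # weight the pool toward vegetables/meat/cereals like a real menu
  cat_weights <- c(0.22, 0.10, 0.14, 0.08, 0.07, 0.08, 0.12, 0.07, 0.04,
                   0.04, 0.04)
  ing_cat <- sample(cats, n_ing, replace = TRUE, prob = cat_weights)
  ing_names <- paste0("ingredient ", sprintf("%03d", seq_len(n_ing)), " ",
                      vapply(strsplit(ing_cat, "[ ,]"), `[`, "", 1))

  energy <- round(stats::runif(n_ing, 15, 400), 1)
  protein <- round(stats::runif(n_ing, 0.2, 30), 2)
  fat <- round(stats::runif(n_ing, 0, 40), 2)
  carb <- round(stats::runif(n_ing, 0, 70), 2)
  fiber <- round(stats::runif(n_ing, 0, 8), 2)
  comp <- tibble(
    ingredient = ing_names, category = ing_cat,
    energy_kcal = energy, protein_g = protein, fat_g = fat,
    carbohydrate_g = carb, fiber_g = fiber
  )
  extras <- extra_nutrient_names()[seq_len(config$n_nutrients - 5)]
  for (nu in extras) {
    vals <- round(stats::runif(n_ing, 0, 100), 2)
    vals[stats::runif(n_ing) < config$missing_rate] <- NA_real_
    comp[[nu]] <- vals
  }
  aux_pool <- tibble(
    ingredient = c("ginger", "garlic", "scallion"),
    category = "vegetables and vegetable products",
    energy_kcal = c(46, 128, 33), protein_g = c(1.3, 4.5, 1.8),
    fat_g = c(0.6, 0.2, 0.3), carbohydrate_g = c(10.3, 27.6, 6.9),
    fiber_g = c(2.7, 1.1, 2.5)
  )
  for (nu in extras) aux_pool[[nu]] <- round(stats::runif(3, 0, 50), 2)
  comp <- bind_rows(comp, aux_pool)
  composition <- as_composition_table(comp, source = "synthetic")

  staple_pool <- ing_names[ing_cat %in%
                             c("cereals", "tubers, starches and their products")]
  protein_pool <- ing_names[ing_cat %in%
                              c("meat and meat products",
                                "poultry and poultry products",
                                "fish, shellfish and molluscs", "eggs",
                                "legumes")]
  veg_pool <- ing_names[ing_cat %in%
                          c("vegetables and vegetable products",
                            "fungi and algae")]
  # guarantee non-empty pools at any config scale
  if (length(staple_pool) == 0) staple_pool <- ing_names[1]
  if (length(protein_pool) == 0) protein_pool <- ing_names[1]
  if (length(veg_pool) == 0) veg_pool <- ing_names[1]

  methods_by_type <- list(
    staple = c("steam", "boil"),
    cooked = c("stir-fry", "steam", "boil", "roast", "deep-fry", "braise"),
    porridge_soup = c("boil")
  )
  rows <- list()
  k <- 0
  for (type in dish_types()) {
    n_dish <- config$menu_size[[type]] %||% 0L
    if (is.na(n_dish) || n_dish < 1) next
    for (j in seq_len(n_dish)) {
      k <- k + 1
      main <- switch(type,
        staple = sample(staple_pool, min(sample(1:2, 1), length(staple_pool))),
        cooked = unique(c(sample(protein_pool, 1),
                          sample(veg_pool, min(sample(1:3, 1), length(veg_pool))))),
        porridge_soup = unique(c(sample(veg_pool, 1),
                                 sample(ing_names, 1)))
      )
      w <- round(stats::runif(length(main), 50, 300))
      ing <- tibble(ingredient = main, weight_g = w, auxiliary = FALSE)
      if (stats::runif(1) < 0.6) {
        aux <- sample(aux_pool$ingredient, sample(1:2, 1))
        ing <- bind_rows(ing, tibble(ingredient = aux,
                                     weight_g = round(stats::runif(length(aux), 2, 10)),
                                     auxiliary = TRUE))
      }
      rows[[k]] <- tibble(
        dish = paste(gsub("_", " ", type), "dish", sprintf("%03d", j)),
        dish_type = type,
        method = sample(methods_by_type[[type]], 1),
        ingredients = list(ing)
      )
    }
  }
  recipes <- bind_rows(rows)

  uncovered <- character(0)
  if (config$n_uncovered_dishes > 0) {
    for (j in seq_len(config$n_uncovered_dishes)) {
      k <- k + 1
      uncovered_ing <- paste("unlisted ingredient", sprintf("%02d", j))
      recipes <- bind_rows(recipes, tibble(
        dish = paste("uncovered dish", sprintf("%02d", j)),
        dish_type = "cooked",
        method = "stir-fry",
        ingredients = list(tibble(
          ingredient = c(sample(veg_pool, 1), uncovered_ing),
          weight_g = c(200, 100), auxiliary = FALSE
        ))
      ))
      uncovered <- c(uncovered, paste("uncovered dish", sprintf("%02d", j)))
    }
  }
  recipes <- as_recipe_db(recipes, source = "synthetic")
  attr(recipes, "uncovered_dishes") <- uncovered
  list(recipes = recipes, composition = composition)
}

#' Generate a synthetic plate-event stream
#'
#' For each consumer, day and meal slot, draws `plates_per_meal` dishes
#' from that consumer's fixed categorical preference distribution over the
#' menu (Dirichlet-distributed weights, drawn once per consumer), with a
#' serving weight uniform in the dish type's configured range and a price
#' proportional to weight. Planted uncovered dishes get zero preference:
#' clean events always pass all four selection filters.
#'
#' When `corruption_rate > 0`, that fraction of rows is corrupted in place,
#' cycling over the four violation kinds (`wrong_meal_slot`,
#' `bad_plate_type`, `unknown_dish`, `missing_ingredient` — the last needs
#' `n_uncovered_dishes >= 1`); the `corruptions` attribute ledgers each
#' corrupted row number and kind.
#'
#' @param config A [sim_config()].
#' @param recipes The `recipe_db` from [generate_food_knowledge()].
#' @return A `plate_events` tibble with attributes `corruptions` (tibble
#'   `row`, `kind`) and `preferences` (tibble `consumer_id`, `dish`,
#'   `weight` — the planted ground truth).
#' @export
generate_events <- function(config, recipes) {
  with_sim_seed(config$seed + 1L, function() generate_events_impl(config, recipes))
}

generate_events_impl <- function(config, recipes) {
  uncovered <- attr(recipes, "uncovered_dishes") %||% character(0)
  menu <- recipes$dish[!recipes$dish %in% uncovered]
  type_of <- stats::setNames(recipes$dish_type, recipes$dish)
  plate_of <- c(staple = 1L, cooked = 2L, porridge_soup = 3L)
  price_rate <- c(staple = 1.0, cooked = 2.5, porridge_soup = 1.5)

  dates <- seq(config$start_date, by = "day", length.out = config$n_days * 2 + 14)
  if (config$working_days_only) {
    dates <- dates[!format(dates, "%u") %in% c("6", "7")]
  }
  dates <- dates[seq_len(config$n_days)]

  consumers <- sprintf("C%04d", seq_len(config$n_consumers))
  pref <- matrix(
    stats::rgamma(config$n_consumers * length(menu),
                  shape = config$preference_concentration),
    nrow = config$n_consumers
  )
  pref <- pref / rowSums(pref)

  n_rows <- config$n_consumers * length(dates) * length(config$meal_slots) *
    config$plates_per_meal
  grid <- expand.grid(
    plate = seq_len(config$plates_per_meal),
    consumer = seq_along(consumers),
    meal_slot = config$meal_slots,
    date = dates,
    stringsAsFactors = FALSE
  )
  dish_idx <- vapply(grid$consumer, function(ci) {
    sample.int(length(menu), 1, prob = pref[ci, ])
  }, integer(1))
  dish <- menu[dish_idx]
  type <- type_of[dish]
  rng <- config$serving_weight_range
  wmin <- vapply(type, function(t) rng[[t]][1], numeric(1))
  wmax <- vapply(type, function(t) rng[[t]][2], numeric(1))
  weight <- round(stats::runif(n_rows, wmin, wmax))
  events <- tibble(
    consumer_id = consumers[grid$consumer],
    dish_name = dish,
    plate_type = unname(plate_of[type]),
    serving_weight_g = weight,
    price = round(weight / 100 * unname(price_rate[type]), 1),
    meal_slot = grid$meal_slot,
    date = grid$date
  )

  kinds <- c("wrong_meal_slot", "bad_plate_type", "unknown_dish",
             "missing_ingredient")
  if (config$corruption_rate == 0 || length(uncovered) == 0) {
    kinds <- setdiff(kinds, "missing_ingredient")
  }
  n_corrupt <- floor(config$corruption_rate * nrow(events))
  ledger <- tibble(row = integer(0), kind = character(0))
  if (n_corrupt > 0) {
    rows <- sort(sample.int(nrow(events), n_corrupt))
    kind <- rep_len(kinds, n_corrupt)
    for (i in seq_len(n_corrupt)) {
      r <- rows[i]
      switch(kind[i],
        wrong_meal_slot = {
          events$meal_slot[r] <- sample(setdiff(meal_slots(),
                                                config$meal_slots), 1)
        },
        bad_plate_type = {
          events$plate_type[r] <- sample(c(0L, 4L, 9L), 1)
        },
        unknown_dish = {
          events$dish_name[r] <- paste("mystery dish", sprintf("%03d", i))
        },
        missing_ingredient = {
          events$dish_name[r] <- sample(uncovered, 1)
        }
      )
    }
    ledger <- tibble(row = rows, kind = kind)
  }
  structure(events, corruptions = ledger,
            preferences = tibble(
              consumer_id = rep(consumers, each = length(menu)),
              dish = rep(menu, times = length(consumers)),
              weight = as.vector(t(pref))
            ),
            class = unique(c("plate_events", class(events))))
}

#' Simulate the individual-level analysis scenario
#'
#' A single consumer observed over `n_days` working days of lunches, with a
#' planted habit: on `n_planted` of the days (chosen at random under the
#' seed) the consumer takes a plate of rice and a bowl of soup alongside
#' the day's cooked dish; on the remaining days only the cooked dish.
#' [food_frequency()] on the result recovers the planted rice (and soup)
#' count exactly, and daily aggregation yields one intake entry per day.
#'
#' @param n_days Observation window in working days. Default 20.
#' @param n_planted Days on which rice + soup are taken. Default 15.
#' @param seed Integer seed.
#' @return List: `knowledge` (recipes + composition), `events`
#'   (a `plate_events` tibble), `consumer_id`, `planted_days` (Dates).
#' @export
simulate_personal_scenario <- function(n_days = 20, n_planted = 15, seed = 1) {
  stopifnot(n_planted <= n_days)
  config <- sim_config(
    n_consumers = 1, n_days = n_days, seed = seed,
    menu_size = c(staple = 1, cooked = 6, porridge_soup = 1),
    plates_per_meal = 1
  )
  knowledge <- generate_food_knowledge(config)
  recipes <- knowledge$recipes
  rice <- recipes$dish[recipes$dish_type == "staple"][1]
  soup <- recipes$dish[recipes$dish_type == "porridge_soup"][1]

  base <- generate_events(config, recipes)
  # keep only cooked-dish draws as the daily base, one per day
  cooked_menu <- recipes$dish[recipes$dish_type == "cooked"]
  base <- with_sim_seed(seed + 2L, function() {
    days <- sort(unique(base$date))
    tibble(
      consumer_id = "C0001",
      dish_name = sample(cooked_menu, length(days), replace = TRUE),
      plate_type = 2L,
      serving_weight_g = round(stats::runif(length(days), 150, 300)),
      price = 5,
      meal_slot = "lunch",
      date = days
    )
  })
  planted_days <- with_sim_seed(seed + 3L, function() {
    sort(sample(base$date, n_planted))
  })
  extras <- bind_rows(
    tibble(consumer_id = "C0001", dish_name = rice, plate_type = 1L,
           serving_weight_g = 200, price = 2, meal_slot = "lunch",
           date = planted_days),
    tibble(consumer_id = "C0001", dish_name = soup, plate_type = 3L,
           serving_weight_g = 250, price = 3, meal_slot = "lunch",
           date = planted_days)
  )
  events <- arrange(bind_rows(base, extras), .data$date, .data$plate_type)
  events <- structure(events,
                      class = unique(c("plate_events", class(events))))
  list(knowledge = knowledge, events = events, consumer_id = "C0001",
       rice_dish = rice, soup_dish = soup, planted_days = planted_days)
}
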