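# Dish decomposition, per-100 g nutrient content, per-serving intake and
# aggregation.

test_that("decomposition splits a serving in raw-weight proportion", {
  db <- tiny_recipes()
  # single ingredient: whole serving
  expect_equal(decompose_dish(get_recipe(db, "plain rice"), 100),
               tibble::tibble(ingredient = "rice", weight_g = 100))
  # 250:150 over 400 at serving 200 -> 125, 75
  parts <- decompose_dish(get_recipe(db, "braised pork"), 200)
  expect_equal(parts$weight_g[parts$ingredient == "pork"], 125)
  expect_equal(parts$weight_g[parts$ingredient == "cabbage"], 75)
})

test_that("auxiliary ingredients are excluded from weights and denominator by default", {
  rec <- as_recipe_db(tibble::tibble(
    dish = "mixed", dish_type = "cooked", method = "stir-fry",
    ingredients = list(tibble::tibble(
      ingredient = c("a", "b", "c", "d"),
      weight_g = c(250, 150, 100, 10),
      auxiliary = c(FALSE, FALSE, FALSE, TRUE)
    ))
  ))[1, ]
  parts <- decompose_dish(rec, 100)
  expect_equal(parts$weight_g[match(c("a", "b", "c"), parts$ingredient)],
               c(50, 30, 20))
  expect_false("d" %in% parts$ingredient)
  with_aux <- decompose_dish(rec, 100, include_auxiliary = TRUE)
  expect_equal(with_aux$weight_g[with_aux$ingredient == "d"],
               10 / 510 * 100)
})

test_that("decomposition conserves mass across random recipes and servings", {
  config <- sim_config(n_consumers = 1, n_days = 1, seed = 21)
  kn <- generate_food_knowledge(config)
  set.seed(22)
  servings <- runif(nrow(kn$recipes), 50, 500)
  for (i in seq_len(nrow(kn$recipes))) {
    parts <- decompose_dish(kn$recipes[i, ], servings[i])
    expect_equal(sum(parts$weight_g), servings[i], tolerance = 1e-9)
  }
})

test_that("degenerate servings and recipes are refused", {
  db <- tiny_recipes()
  expect_error(decompose_dish(get_recipe(db, "plain rice"), 0),
               class = "dietledger_validation_error")
  expect_error(decompose_dish(get_recipe(db, "plain rice"), -5),
               class = "dietledger_validation_error")
})

test_that("a single-ingredient dish has its ingredient's nutrient vector", {
  v <- nutrient_content_per_100g(get_recipe(tiny_recipes(), "plain rice"),
                                 tiny_composition())
  rice <- lookup_ingredient(tiny_composition(), "rice")
  for (nu in core_nutrients()) expect_equal(v[[nu]], rice[[nu]])
})

test_that("a 50:50 blend lands at the nutrient midpoint", {
  comp <- as_composition_table(tibble::tibble(
    ingredient = c("x", "y"), category = "other",
    energy_kcal = c(100, 300), protein_g = c(2, 4), fat_g = c(1, 3),
    carbohydrate_g = c(10, 30), fiber_g = c(0, 2)
  ))
  rec <- as_recipe_db(tibble::tibble(
    dish = "blend", dish_type = "cooked", method = "boil",
    ingredients = list(tibble::tibble(ingredient = c("x", "y"),
                                      weight_g = c(120, 120),
                                      auxiliary = FALSE))
  ))[1, ]
  v <- nutrient_content_per_100g(rec, comp)
  expect_equal(v$energy_kcal, 200)
  expect_equal(v$carbohydrate_g, 20)
})

test_that("per-100 g content matches the brute-force oracle on generated recipes", {
  for (seed in c(31, 32)) {
    kn <- generate_food_knowledge(sim_config(seed = seed))
    for (i in seq_len(nrow(kn$recipes))) {
      got <- suppressWarnings(
        nutrient_content_per_100g(kn$recipes[i, ], kn$composition)
      )
      want <- oracle_per100g(kn$recipes[i, ], kn$composition)
      for (nu in names(want)) {
        expect_equal(got[[nu]], unname(want[nu]), tolerance = 1e-9)
      }
    }
  }
})

test_that("an uncovered ingredient raises a lookup error naming it", {
  rec <- as_recipe_db(tibble::tibble(
    dish = "exotic", dish_type = "cooked", method = "raw",
    ingredients = list(tibble::tibble(ingredient = c("tomato", "sea grapes"),
                                      weight_g = c(100, 50),
                                      auxiliary = FALSE))
  ))[1, ]
  expect_error(nutrient_content_per_100g(rec, tiny_composition()),
               "sea grapes", class = "dietledger_lookup_error")
})

test_that("nutrients absent for any contributing ingredient stay absent, with warning", {
  comp <- tibble::as_tibble(tiny_composition())
  comp$fiber_g[comp$ingredient == "pork"] <- NA_real_
  comp <- as_composition_table(comp)
  rec <- get_recipe(tiny_recipes(), "braised pork")
  expect_warning(v <- nutrient_content_per_100g(rec, comp), "fiber_g")
  expect_true(is.na(v$fiber_g))
  expect_equal(attr(v, "absent_nutrients"), "fiber_g")
  expect_false(is.na(v$energy_kcal))
})

test_that("intake scales exactly linearly in serving weight", {
  db <- tiny_recipes()
  comp <- tiny_composition()
  ev <- tiny_events()[2, ]
  ev$serving_weight_g <- 100
  base <- intake_for_event(ev, db, comp)
  per100 <- nutrient_content_per_100g(get_recipe(db, ev$dish_name), comp)
  for (nu in core_nutrients()) expect_equal(base[[nu]], per100[[nu]])
  for (k in c(0.5, 2, 3.7)) {
    scaled_ev <- ev
    scaled_ev$serving_weight_g <- 100 * k
    scaled <- intake_for_event(scaled_ev, db, comp)
    for (nu in core_nutrients()) expect_equal(scaled[[nu]], k * base[[nu]])
  }
})

test_that("event-stream intake totals match the oracle", {
  config <- sim_config(n_consumers = 2, n_days = 10, seed = 41)
  kn <- generate_food_knowledge(config)
  ev <- generate_events(config, kn$recipes)
  records <- intake_records(ev, kn$recipes, kn$composition)
  expect_equal(nrow(records), nrow(ev))
  want_energy <- vapply(seq_len(nrow(ev)), function(i) {
    rec <- get_recipe(kn$recipes, ev$dish_name[i])
    unname(oracle_per100g(rec, kn$composition)["energy_kcal"]) *
      ev$serving_weight_g[i] / 100
  }, numeric(1))
  expect_equal(records$energy_kcal, want_energy, tolerance = 1e-9)
})

test_that("aggregation sums component-wise over the requested grouping", {
  db <- tiny_recipes()
  comp <- tiny_composition()
  ev <- tiny_events()
  ev$date <- as.Date("2016-01-05") # all same day
  records <- intake_records(ev, db, comp)
  daily <- aggregate_intake(records, by = "consumer_date")
  expect_equal(nrow(daily), 1)
  expect_equal(daily$n_events, 4)
  expect_equal(daily$energy_kcal, sum(records$energy_kcal))

  single <- aggregate_intake(records[1, ], by = "consumer_date")
  expect_equal(single$protein_g, records$protein_g[1])
})

test_that("aggregates are invariant to partitioning the records", {
  config <- sim_config(n_consumers = 5, n_days = 10, seed = 51)
  kn <- generate_food_knowledge(config)
  ev <- generate_events(config, kn$recipes)
  records <- intake_records(ev, kn$recipes, kn$composition)
  whole <- suppressWarnings(aggregate_intake(records, by = "consumer"))
  set.seed(52)
  split <- sample(c(TRUE, FALSE), nrow(records), replace = TRUE)
  numcols <- setdiff(names(whole), "consumer_id")
  parts <- suppressWarnings(dplyr::bind_rows(
    aggregate_intake(records[split, ], by = "consumer"),
    aggregate_intake(records[!split, ], by = "consumer")
  )) |>
    dplyr::group_by(consumer_id) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(numcols), sum),
                     .groups = "drop") |>
    dplyr::arrange(consumer_id)
  expect_equal(plain_df(parts), plain_df(whole))
})

test_that("absent nutrients propagate through aggregation instead of becoming zero", {
  comp <- tibble::as_tibble(tiny_composition())
  comp$fiber_g[comp$ingredient == "pork"] <- NA_real_
  comp <- as_composition_table(comp)
  records <- suppressWarnings(
    intake_records(tiny_events(), tiny_recipes(), comp)
  )
  expect_warning(total <- aggregate_intake(records, by = "consumer"), "fiber_g")
  expect_true(is.na(total$fiber_g))
  expect_false(is.na(total$energy_kcal))
})

test_that("daily series dates are strictly increasing per consumer", {
  config <- sim_config(n_consumers = 3, n_days = 15, seed = 61)
  kn <- generate_food_knowledge(config)
  ev <- generate_events(config, kn$recipes)
  series <- suppressWarnings(aggregate_intake(
    intake_records(ev, kn$recipes, kn$composition), by = "consumer_date"))
  by_consumer <- split(series$date, series$consumer_id)
  for (d in by_consumer) expect_true(all(diff(d) > 0))
})
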