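# Population- and individual-level reports.

# recipe database with a prescribed number of one-ingredient dishes per
# (dish type, method) combination
counts_db <- function(spec) {
  rows <- purrr::pmap(spec, function(dish_type, method, n) {
    tibble::tibble(
      dish = paste(dish_type, method, seq_len(n)),
      dish_type = dish_type, method = method,
      ingredients = list(tibble::tibble(ingredient = "rice", weight_g = 100,
                                        auxiliary = FALSE))
    )
  })
  as_recipe_db(dplyr::bind_rows(rows))
}

test_that("published dish-type shares reproduce from the same counts", {
  db <- counts_db(tibble::tibble(
    dish_type = c("staple", "cooked", "porridge_soup"),
    method = c("steam", "stir-fry", "boil"),
    n = c(83, 391, 15)
  ))
  rep <- dish_type_distribution(db$dish, db)
  expect_equal(attr(rep, "total"), 489)
  expect_equal(rep$count[rep$label == "staple"], 83)
  expect_equal(rep$percentage[rep$label == "staple"], 17.0)
  expect_equal(rep$percentage[rep$label == "cooked"], 80.0)
  # 15/489 rounds to 3.1 under the package's stated 1-decimal rule
  expect_equal(rep$percentage[rep$label == "porridge_soup"], 3.1)
})

test_that("a single dish yields 100% in its type and zero rows elsewhere", {
  db <- counts_db(tibble::tibble(dish_type = "cooked", method = "stir-fry", n = 1))
  rep <- dish_type_distribution(db$dish, db)
  expect_equal(nrow(rep), 3) # zero-count categories still listed
  expect_equal(rep$percentage[rep$label == "cooked"], 100.0)
  expect_equal(rep$count[rep$label != "cooked"], c(0L, 0L))
})

test_that("dish-type tallies match a brute-force oracle on random menus", {
  set.seed(71)
  spec <- tibble::tibble(
    dish_type = rep(dish_types(), each = 2),
    method = rep(c("steam", "boil"), 3),
    n = sample(1:20, 6)
  )
  db <- counts_db(spec)
  rep <- dish_type_distribution(db$dish, db)
  want <- oracle_tally(db$dish_type)
  got <- as.data.frame(rep[rep$count > 0, c("label", "count")])
  expect_equal(got[order(got$label), ], want[order(want$label), ],
               ignore_attr = TRUE)
  expect_equal(sum(rep$count), attr(rep, "total"))
})

test_that("preparation methods are tallied over cooked dishes by default", {
  db <- counts_db(tibble::tibble(
    dish_type = c("cooked", "cooked", "staple"),
    method = c("stir-fry", "steam", "boil"),
    n = c(6, 2, 4)
  ))
  rep <- preparation_method_distribution(db$dish, db)
  expect_equal(attr(rep, "total"), 8) # staple dishes excluded
  expect_equal(rep$percentage[rep$label == "stir-fry"], 75.0)
  all_rep <- preparation_method_distribution(db$dish, db, restrict_to = "all")
  expect_equal(attr(all_rep, "total"), 12)
  expect_equal(all_rep$count[all_rep$label == "boil"], 4L)
})

test_that("an empty dish set yields an empty report with total zero", {
  rep <- preparation_method_distribution(character(0), tiny_recipes())
  expect_equal(nrow(rep), 0)
  expect_equal(attr(rep, "total"), 0)
})

test_that("method tallies match a brute-force oracle", {
  set.seed(72)
  methods <- c("stir-fry", "steam", "boil", "roast", "deep-fry", "braise")
  spec <- tibble::tibble(dish_type = "cooked", method = methods,
                         n = sample(1:15, 6))
  db <- counts_db(spec)
  rep <- preparation_method_distribution(db$dish, db)
  want <- oracle_tally(rep(methods, spec$n))
  got <- as.data.frame(rep[rep$count > 0, c("label", "count")])
  expect_equal(got[order(got$label), ], want[order(want$label), ],
               ignore_attr = TRUE)
})

test_that("ingredient categories count distinct ingredient kinds once", {
  db <- tiny_recipes()
  comp <- tiny_composition()
  # tomato egg: tomato (veg) + egg (eggs); tofu soup: tofu (legumes) + cabbage (veg)
  rep <- ingredient_category_distribution(c("tomato egg", "tofu soup"), db, comp)
  expect_equal(attr(rep, "total"), 4)
  expect_equal(rep$count[rep$label == "vegetables and vegetable products"], 2L)
  expect_equal(rep$percentage[rep$label == "eggs"], 25.0)

  # duplicating a dish in the input must not change the report
  dup <- ingredient_category_distribution(
    c("tomato egg", "tofu soup", "tomato egg"), db, comp)
  expect_equal(plain_df(dup), plain_df(rep))

  # shared ingredient across dishes counted once: cabbage in both
  shared <- ingredient_category_distribution(c("braised pork", "tofu soup"),
                                             db, comp)
  expect_equal(attr(shared, "total"), 3) # pork, cabbage, tofu
})

test_that("category shares match a set-union oracle on generated menus", {
  kn <- generate_food_knowledge(sim_config(seed = 81))
  rep <- ingredient_category_distribution(kn$recipes$dish, kn$recipes,
                                          kn$composition)
  comp <- tibble::as_tibble(kn$composition)
  kinds <- unique(unlist(lapply(kn$recipes$ingredients, function(i) {
    i$ingredient[!i$auxiliary]
  })))
  want <- oracle_tally(comp$category[match(kinds, comp$ingredient)])
  got <- as.data.frame(rep[, c("label", "count")])
  expect_equal(got[order(got$label), ], want[order(want$label), ],
               ignore_attr = TRUE)
  expect_equal(attr(rep, "total"), length(kinds))
})

test_that("displayed percentages close to 100 within rounding slack", {
  for (seed in 82:84) {
    kn <- generate_food_knowledge(sim_config(seed = seed))
    rep <- ingredient_category_distribution(kn$recipes$dish, kn$recipes,
                                            kn$composition)
    expect_lt(abs(sum(rep$percentage) - 100), 0.1 * nrow(rep) + 1e-9)
    expect_equal(sum(rep$count), attr(rep, "total"))
  }
})

test_that("food frequency counts one consumer's events inside the window", {
  ev <- tiny_events()
  one <- food_frequency(ev[1, ], "C1")
  expect_equal(plain_df(one),
               data.frame(dish_name = "plain rice", times_chosen = 1L))

  windowed <- food_frequency(ev, "C1",
                             window = as.Date(c("2016-01-05", "2016-01-06")))
  expect_equal(sum(windowed$times_chosen), 2)
  expect_false("tofu soup" %in% windowed$dish_name)

  expect_equal(nrow(food_frequency(ev, "nobody")), 0)
})

test_that("food frequency is additive over adjoining windows", {
  config <- sim_config(n_consumers = 3, n_days = 20, seed = 91)
  kn <- generate_food_knowledge(config)
  ev <- generate_events(config, kn$recipes)
  mid <- sort(unique(ev$date))[10]
  whole <- food_frequency(ev, "C0001")
  left <- food_frequency(ev, "C0001", window = c(min(ev$date), mid))
  right <- food_frequency(ev, "C0001", window = c(mid + 1, max(ev$date)))
  merged <- dplyr::bind_rows(tibble::as_tibble(left), tibble::as_tibble(right)) |>
    dplyr::group_by(dish_name) |>
    dplyr::summarise(times_chosen = sum(times_chosen), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(times_chosen), dish_name)
  expect_equal(plain_df(merged), plain_df(whole))
})

test_that("report rows order by descending count with alphabetical tie-break", {
  db <- counts_db(tibble::tibble(
    dish_type = c("staple", "cooked", "porridge_soup"),
    method = c("steam", "stir-fry", "boil"),
    n = c(4, 9, 4)
  ))
  rep <- dish_type_distribution(db$dish, db)
  expect_equal(rep$label, c("cooked", "porridge_soup", "staple"))
})

test_that("autoplot methods return ggplot objects", {
  db <- tiny_recipes()
  rep <- dish_type_distribution(db$dish, db)
  expect_s3_class(autoplot(rep), "ggplot")
  ff <- food_frequency(tiny_events(), "C1")
  expect_s3_class(autoplot(ff), "ggplot")
  series <- aggregate_intake(
    intake_records(tiny_events(), db, tiny_composition()),
    by = "consumer_date")
  expect_s3_class(autoplot(series), "ggplot")
})
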