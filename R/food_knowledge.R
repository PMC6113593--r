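# Food knowledge: the composition table and the recipe database.
#
# The composition table maps raw ingredients to nutrient amounts per 100 g
# edible portion; the recipe database breaks a named dish down into raw
# ingredients with weights. Together they let a consumed dish be decomposed
# first to ingredients and then to nutrients.

#' Read a food composition table
#'
#' Reads a delimited table (CSV or TSV, auto-detected from the file
#' extension) mapping ingredients to food-group categories and nutrient
#' amounts per 100 g edible portion. The schema emulates the China Food
#' Composition Database: columns `ingredient`, `category`, the five core
#' nutrients (see [core_nutrients()]) and optionally further nutrient
#' columns, up to the 23-nutrient set.
#'
#' Empty cells parse to `NA`, an explicit "not measured" marker distinct
#' from a measured zero; downstream summation propagates `NA` rather than
#' treating it as zero content. Rows with any negative nutrient value are
#' rejected (dropped with a warning and recorded in the `rejects`
#' attribute): nutrient amounts are physically non-negative.
#'
#' @param path Path to a CSV (`.csv`) or TSV (`.tsv`/`.txt`) file with a
#'   header row, UTF-8 encoded.
#' @return A tibble of class `food_composition` with one row per ingredient,
#'   keyed by normalized ingredient name. Attributes: `nutrients` (nutrient
#'   column names), `source` (file path), `rejects` (tibble of dropped rows).
#' @seealso [write_composition_table()], [lookup_ingredient()]
#' @export
read_composition_table <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("composition table not found: ", path), class = "dietledger_io_error")
  }
  reader <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) {
    readr::read_tsv
  } else {
    readr::read_csv
  }
  raw <- reader(path, show_col_types = FALSE, progress = FALSE)
  as_composition_table(raw, source = path)
}

#' Build a composition table from a data frame
#'
#' Validates schema, category vocabulary, key uniqueness and nutrient
#' non-negativity, and stamps the `food_composition` class. Used by
#' [read_composition_table()] and by the simulator.
#'
#' @param x Data frame with columns `ingredient`, `category` and nutrient
#'   columns including all of [core_nutrients()].
#' @param source Character label recording where the table came from.
#' @return A `food_composition` tibble (see [read_composition_table()]).
#' @export
as_composition_table <- function(x, source = "in-memory") {
  x <- as_tibble(x)
  required <- c("ingredient", "category", core_nutrients())
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(
      paste0("composition table is missing required column(s): ",
             paste(missing_cols, collapse = ", ")),
      class = "dietledger_schema_error"
    )
  }
  nutrients <- setdiff(names(x), c("ingredient", "category"))
  x$ingredient <- normalize_food_name(x$ingredient)
  x$category <- trimws(tolower(x$category))

  dup <- unique(x$ingredient[duplicated(x$ingredient)])
  if (length(dup) > 0) {
    abort(
      paste0("duplicate ingredient key(s): ", paste(dup, collapse = ", ")),
      class = "dietledger_duplicate_key_error"
    )
  }
  bad_cat <- setdiff(unique(x$category), food_categories())
  if (length(bad_cat) > 0) {
    abort(
      paste0("unknown food category: ", paste(bad_cat, collapse = ", ")),
      class = "dietledger_vocabulary_error"
    )
  }

  neg <- rowSums(as.matrix(x[nutrients]) < 0, na.rm = TRUE) > 0
  rejects <- x[neg, , drop = FALSE]
  if (any(neg)) {
    warn(paste0(sum(neg), " row(s) with negative nutrient values rejected: ",
                paste(rejects$ingredient, collapse = ", ")))
    x <- x[!neg, , drop = FALSE]
  }

  structure(
    x,
    nutrients = nutrients,
    source = source,
    rejects = rejects,
    class = c("food_composition", class(x))
  )
}

#' Write a composition table to delimited text
#'
#' Inverse of [read_composition_table()]: values round-trip exactly as
#' parsed, with `NA` nutrient cells written as empty fields.
#'
#' @param x A `food_composition` tibble.
#' @param path Output path; `.tsv`/`.txt` writes tab-separated, anything
#'   else comma-separated.
#' @return `path`, invisibly.
#' @export
write_composition_table <- function(x, path) {
  writer <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) {
    readr::write_tsv
  } else {
    readr::write_csv
  }
  writer(as_tibble(x), path, na = "", progress = FALSE)
  invisible(path)
}

#' Nutrient column names of a composition table
#'
#' @param table A `food_composition` tibble.
#' @return Character vector of nutrient column names.
#' @export
composition_nutrients <- function(table) {
  attr(table, "nutrients") %||% setdiff(names(table), c("ingredient", "category"))
}

#' Look up one ingredient in a composition table
#'
#' Exact match after name normalization.
#'
#' @param table A `food_composition` tibble.
#' @param name Ingredient name (normalized internally).
#' @return One-row tibble with the ingredient's category and per-100 g
#'   nutrient amounts.
#' @export
lookup_ingredient <- function(table, name) {
  key <- normalize_food_name(name)
  hit <- as_tibble(table)[as_tibble(table)$ingredient == key, , drop = FALSE]
  if (nrow(hit) != 1L) {
    abort(paste0("ingredient not found in composition table: ", key),
          class = "dietledger_lookup_error")
  }
  hit
}

# Recipe database --------------------------------------------------------------

#' Read a recipe database
#'
#' Reads a structured recipe document (JSON or YAML, auto-detected from the
#' extension) describing each dish: normalized name, dish type (one of
#' `staple`, `cooked`, `porridge_soup`), preparation method (controlled
#' vocabulary, see Details) and an ingredient list with raw weights in
#' grams. Condiment-scale ingredients (e.g. ginger, garlic) carry an
#' `auxiliary: true` flag set by the recipe author; they are excluded from
#' nutrient calculation by default.
#'
#' The document has a top-level `schema_version` field and a `recipes`
#' array; each recipe record has fields `dish`, `dish_type`, `method` and
#' `ingredients` (each with `ingredient`, `weight_g`, optional `auxiliary`).
#'
#' @details Preparation methods: stir-fry, steam, boil, roast, deep-fry,
#'   braise, raw, other.
#'
#' @param path Path to a `.json` or `.yaml`/`.yml` file.
#' @return A nested tibble of class `recipe_db`: one row per dish with
#'   columns `dish`, `dish_type`, `method` and a list-column `ingredients`
#'   of tibbles (`ingredient`, `weight_g`, `auxiliary`).
#' @seealso [write_recipe_db()], [as_recipe_db()], [get_recipe()]
#' @export
read_recipe_db <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("recipe database not found: ", path), class = "dietledger_io_error")
  }
  doc <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  }
  recs <- doc$recipes %||% abort("recipe document has no 'recipes' field",
                                 class = "dietledger_schema_error")
  rows <- purrr::map(recs, function(r) {
    ing <- purrr::map(r$ingredients, function(i) {
      tibble(
        ingredient = as.character(i$ingredient),
        weight_g = as.numeric(i$weight_g),
        auxiliary = isTRUE(i$auxiliary)
      )
    })
    tibble(
      dish = as.character(r$dish),
      dish_type = as.character(r$dish_type),
      method = as.character(r$method),
      ingredients = list(bind_rows(ing))
    )
  })
  as_recipe_db(bind_rows(rows), source = path)
}

#' Build a recipe database from a data frame
#'
#' Validates the dish-type and method vocabularies, normalizes names, and
#' enforces the structural invariants: every recipe has at least one
#' non-auxiliary ingredient with positive total weight, all weights are
#' positive, and dish keys are unique.
#'
#' @param x Data frame with columns `dish`, `dish_type`, `method`,
#'   `ingredients` (list of data frames with `ingredient`, `weight_g` and
#'   optionally `auxiliary`).
#' @param source Character label for provenance.
#' @return A `recipe_db` nested tibble (see [read_recipe_db()]).
#' @export
as_recipe_db <- function(x, source = "in-memory") {
  x <- as_tibble(x)
  required <- c("dish", "dish_type", "method", "ingredients")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("recipe database is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "dietledger_schema_error")
  }
  x$dish <- normalize_food_name(x$dish)

  bad_type <- setdiff(unique(x$dish_type), dish_types())
  if (length(bad_type) > 0) {
    abort(paste0("unknown dish type: ", paste(bad_type, collapse = ", ")),
          class = "dietledger_vocabulary_error")
  }
  bad_method <- setdiff(unique(x$method), preparation_methods())
  if (length(bad_method) > 0) {
    abort(paste0("unknown preparation method: ",
                 paste(bad_method, collapse = ", ")),
          class = "dietledger_vocabulary_error")
  }
  dup <- unique(x$dish[duplicated(x$dish)])
  if (length(dup) > 0) {
    abort(paste0("duplicate dish key(s): ", paste(dup, collapse = ", ")),
          class = "dietledger_duplicate_key_error")
  }

  x$ingredients <- purrr::map2(x$ingredients, x$dish, function(ing, dish) {
    ing <- as_tibble(ing)
    if (!"auxiliary" %in% names(ing)) ing$auxiliary <- FALSE
    ing$ingredient <- normalize_food_name(ing$ingredient)
    ing$weight_g <- as.numeric(ing$weight_g)
    ing$auxiliary <- as.logical(ing$auxiliary)
    if (nrow(ing) == 0 || any(!is.finite(ing$weight_g)) || any(ing$weight_g <= 0)) {
      abort(paste0("recipe '", dish, "': every ingredient needs a positive weight"),
            class = "dietledger_validation_error")
    }
    if (sum(ing$weight_g[!ing$auxiliary]) <= 0) {
      abort(paste0("recipe '", dish,
                   "' has no non-auxiliary ingredient with positive weight"),
            class = "dietledger_validation_error")
    }
    ing[c("ingredient", "weight_g", "auxiliary")]
  })

  structure(x, source = source, schema_version = "1.0",
            class = c("recipe_db", class(x)))
}

#' Write a recipe database to JSON or YAML
#'
#' @param x A `recipe_db` tibble.
#' @param path Output path; `.yaml`/`.yml` writes YAML, anything else JSON.
#' @return `path`, invisibly.
#' @export
write_recipe_db <- function(x, path) {
  recs <- purrr::pmap(
    list(x$dish, x$dish_type, x$method, x$ingredients),
    function(dish, dish_type, method, ingredients) {
      list(
        dish = dish, dish_type = dish_type, method = method,
        ingredients = purrr::pmap(
          list(ingredients$ingredient, ingredients$weight_g, ingredients$auxiliary),
          function(i, w, a) list(ingredient = i, weight_g = w, auxiliary = a)
        )
      )
    }
  )
  doc <- list(schema_version = "1.0", recipes = recs)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(doc, path)
  } else {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Fetch one recipe by dish name
#'
#' @param recipes A `recipe_db` tibble.
#' @param dish Dish name (normalized internally).
#' @return One-row `recipe_db` slice.
#' @export
get_recipe <- function(recipes, dish) {
  key <- normalize_food_name(dish)
  hit <- recipes[recipes$dish == key, , drop = FALSE]
  if (nrow(hit) != 1L) {
    abort(paste0("dish not found in recipe database: ", key),
          class = "dietledger_lookup_error")
  }
  hit
}

#' Check that a recipe's ingredients resolve in a composition table
#'
#' A recipe is covered when every ingredient that enters the nutrient
#' calculation has an entry in the composition table. Auxiliary ingredients
#' are only checked when `include_auxiliary = TRUE`, matching the engine
#' configuration that would use them.
#'
#' @param recipe A one-row `recipe_db` slice (see [get_recipe()]).
#' @param table A `food_composition` tibble.
#' @param include_auxiliary Check auxiliary (condiment-scale) ingredients
#'   too? Default `FALSE`.
#' @return Character vector of missing ingredient names; empty when fully
#'   covered.
#' @export
validate_recipe_coverage <- function(recipe, table, include_auxiliary = FALSE) {
  ing <- recipe$ingredients[[1]]
  if (!include_auxiliary) ing <- ing[!ing$auxiliary, , drop = FALSE]
  setdiff(unique(ing$ingredient), as_tibble(table)$ingredient)
}

#' Coverage report for a whole recipe database
#'
#' @param recipes A `recipe_db` tibble.
#' @param table A `food_composition` tibble.
#' @inheritParams validate_recipe_coverage
#' @return Tibble with columns `dish`, `missing` (list-column of missing
#'   ingredient names) and `covered` (logical).
#' @export
coverage_report <- function(recipes, table, include_auxiliary = FALSE) {
  missing <- purrr::map(seq_len(nrow(recipes)), function(i) {
    validate_recipe_coverage(recipes[i, ], table, include_auxiliary)
  })
  tibble(
    dish = recipes$dish,
    missing = missing,
    covered = purrr::map_lgl(missing, ~ length(.x) == 0)
  )
}
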