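# Population- and individual-level reports: dish-type, preparation-method
# and ingredient-category distributions, and per-consumer food frequency.
#
# Distribution denominators are over UNIQUE dishes (or distinct ingredient
# kinds), not event counts: the population-level question is "what kinds of
# food does the menu-as-consumed contain". An events-weighted variant is
# available via the `weights` argument.

new_distribution_report <- function(counts, labels_all, total, denominator) {
  # counts: named integer vector over observed labels; labels_all: full label
  # set to report (zero rows included) or NULL to report observed labels only
  if (!is.null(labels_all)) {
    full <- stats::setNames(rep(0L, length(labels_all)), labels_all)
    full[names(counts)] <- counts
    counts <- full
  }
  out <- tibble(
    label = names(counts),
    count = as.integer(counts),
    percentage = if (total > 0) {
      round_half_up(as.integer(counts) / total * 100, 1)
    } else {
      numeric(length(counts))
    }
  )
  if (total == 0) out <- out[0, ]
  out <- arrange(out, desc(.data$count), .data$label)
  structure(out, total = total, denominator = denominator,
            class = unique(c("distribution_report", class(out))))
}

#' @export
print.distribution_report <- function(x, ...) {
  cat("Distribution over ", attr(x, "denominator"),
      " (total ", attr(x, "total"), ")\n", sep = "")
  NextMethod()
}

#' Distribution of dish types over a set of dishes
#'
#' Tallies the unique dishes of a menu-as-consumed into the three dish
#' types (staple, cooked, porridge/soup) and reports counts with
#' percentages at 1-decimal rounding. Zero-count types are still listed.
#'
#' @param dishes Character vector of dish names; de-duplicated after
#'   normalization (the unit is the unique dish). Alternatively a
#'   `plate_events` tibble, whose distinct `dish_name`s are used.
#' @param recipes A `recipe_db` tibble resolving every dish (else a lookup
#'   error).
#' @param weights Optional named numeric vector of per-dish weights (e.g.
#'   event counts) for an events-weighted variant; default `NULL` weights
#'   every unique dish equally.
#' @return A `distribution_report` tibble: `label`, `count`, `percentage`,
#'   ordered by descending count with alphabetical tie-break; attributes
#'   `total` and `denominator`.
#' @export
dish_type_distribution <- function(dishes, recipes, weights = NULL) {
  dishes <- extract_dishes(dishes)
  types <- dish_property(dishes, recipes, "dish_type")
  counts <- tally_by(types, dishes, weights)
  new_distribution_report(counts, dish_types(), sum(counts),
                          "unique dishes by dish type")
}

#' Distribution of preparation methods over a set of dishes
#'
#' As [dish_type_distribution()], keyed by the preparation-method
#' vocabulary. By default the tally is restricted to cooked dishes — the
#' population-level preparation question concerns the cooked component of
#' the meal; pass `restrict_to = "all"` for the full menu.
#'
#' @inheritParams dish_type_distribution
#' @param restrict_to A dish type to restrict to, or `"all"`. Default
#'   `"cooked"`.
#' @return A `distribution_report` over the method vocabulary; empty input
#'   yields an empty report with total 0.
#' @export
preparation_method_distribution <- function(dishes, recipes,
                                            restrict_to = "cooked",
                                            weights = NULL) {
  restrict_to <- match.arg(restrict_to, c(dish_types(), "all"))
  dishes <- extract_dishes(dishes)
  if (restrict_to != "all") {
    types <- dish_property(dishes, recipes, "dish_type")
    keep <- types == restrict_to
    dishes <- dishes[keep]
  }
  methods <- dish_property(dishes, recipes, "method")
  counts <- tally_by(methods, dishes, weights)
  new_distribution_report(counts, preparation_methods(), sum(counts),
                          paste0("unique ", restrict_to,
                                 " dishes by preparation method"))
}

#' Distribution of ingredient categories across a set of dishes
#'
#' Counts DISTINCT ingredient kinds per food-group category across the
#' union of the dishes' non-auxiliary ingredients: an ingredient used by
#' many dishes counts once. Percentages are over the total number of
#' distinct ingredient kinds.
#'
#' @inheritParams dish_type_distribution
#' @param table A `food_composition` tibble covering all counted
#'   ingredients (else a lookup error).
#' @param include_auxiliary Count auxiliary ingredients? Default `FALSE`.
#' @return A `distribution_report` over the observed categories.
#' @export
ingredient_category_distribution <- function(dishes, recipes, table,
                                             include_auxiliary = FALSE) {
  dishes <- extract_dishes(dishes)
  ing <- purrr::map(dishes, function(d) {
    i <- get_recipe(recipes, d)$ingredients[[1]]
    if (!include_auxiliary) i <- i[!i$auxiliary, , drop = FALSE]
    i$ingredient
  })
  kinds <- unique(unlist(ing))
  cats <- purrr::map_chr(kinds, function(k) lookup_ingredient(table, k)$category)
  counts <- table_counts(cats)
  new_distribution_report(counts, NULL, length(kinds),
                          "distinct ingredient kinds by category")
}

#' Food frequency table for one consumer
#'
#' Counts how often each dish was chosen by a consumer within a date
#' window, descending count with alphabetical tie-break. An unknown
#' consumer yields an empty table.
#'
#' @param events A `plate_events` tibble.
#' @param consumer Consumer ID.
#' @param window Length-2 date vector `c(start, end)` (inclusive); default
#'   spans the consumer's events.
#' @return Tibble of class `frequency_table` with columns `dish_name` and
#'   `times_chosen`; attributes `consumer_id` and `window`.
#' @export
food_frequency <- function(events, consumer, window = NULL) {
  x <- as_tibble(events)
  x <- x[x$consumer_id == consumer, , drop = FALSE]
  if (is.null(window)) {
    window <- if (nrow(x) > 0) range(x$date) else as.Date(c(NA, NA))
  }
  window <- as.Date(window)
  x <- x[!is.na(x$date) & x$date >= window[1] & x$date <= window[2], ,
         drop = FALSE]
  out <- x |>
    count(.data$dish_name, name = "times_chosen") |>
    arrange(desc(.data$times_chosen), .data$dish_name)
  structure(out, consumer_id = consumer, window = window,
            class = unique(c("frequency_table", class(out))))
}

# helpers ----------------------------------------------------------------------

extract_dishes <- function(dishes) {
  if (is.data.frame(dishes)) dishes <- dishes$dish_name
  unique(normalize_food_name(dishes))
}

dish_property <- function(dishes, recipes, field) {
  purrr::map_chr(dishes, function(d) get_recipe(recipes, d)[[field]])
}

tally_by <- function(groups, dishes, weights) {
  if (is.null(weights)) {
    table_counts(groups)
  } else {
    w <- weights[dishes]
    w[is.na(w)] <- 0
    out <- tapply(w, groups, sum)
    stats::setNames(as.integer(out), names(out))
  }
}

table_counts <- function(x) {
  if (length(x) == 0) return(stats::setNames(integer(0), character(0)))
  tab <- table(x)
  stats::setNames(as.integer(tab), names(tab))
}
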