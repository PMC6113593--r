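# Plate events: ingesting RFID consumption records and the four-stage
# record selection procedure.
#
# One plate event is the atomic unit of dietary data: one consumer taking
# one plate of one dish at one meal. Selection keeps, in order, (1) records
# from the requested meal slot (lunch by default), (2) records on a valid
# RFID plate type, (3) records whose dish resolves in the recipe database,
# (4) records whose recipe is fully covered by the composition table.

event_columns <- function() {
  c("consumer_id", "dish_name", "plate_type", "serving_weight_g",
    "price", "meal_slot", "date")
}

#' Read a plate-event file
#'
#' Reads a CSV of plate events with columns `consumer_id`, `dish_name`,
#' `plate_type` (1 = staple, 2 = cooked dish, 3 = soup), `serving_weight_g`,
#' `price`, `meal_slot` (breakfast/lunch/supper) and `date` (ISO-8601).
#' Valid rows are returned in input order; invalid rows are never silently
#' dropped — they are collected into a rejects report (attribute `rejects`,
#' also via [event_rejects()]) with the input row number and the first
#' failed check as the reason.
#'
#' Row checks, in order: `plate_type` in 1–3 (reason `plate_type`),
#' `serving_weight_g` > 0 (`serving_weight`), `price` >= 0 (`price`),
#' `meal_slot` in the three-slot vocabulary (`meal_slot`), parseable date
#' (`date`).
#'
#' @param path Path to the events CSV.
#' @return Tibble of class `plate_events`, one row per valid event, with a
#'   `rejects` attribute (tibble: `row`, `reason`).
#' @section Errors: an unreadable file raises an I/O error; more than 50%
#'   of rows rejected raises a hard error, since that indicates a schema
#'   mismatch rather than scattered corruption.
#' @export
read_plate_events <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("events file not found: ", path), class = "dietledger_io_error")
  }
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      consumer_id = readr::col_character(),
      dish_name = readr::col_character(),
      plate_type = readr::col_integer(),
      serving_weight_g = readr::col_double(),
      price = readr::col_double(),
      meal_slot = readr::col_character(),
      date = readr::col_character()
    ),
    progress = FALSE
  )
  missing_cols <- setdiff(event_columns(), names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("events file is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "dietledger_schema_error")
  }
  as_plate_events(raw)
}

#' Validate a data frame of plate events
#'
#' Applies the same row checks as [read_plate_events()] to an in-memory
#' data frame. Dish names are normalized; valid rows keep their input
#' order.
#'
#' @param x Data frame with the event columns (see [read_plate_events()]).
#' @return A `plate_events` tibble with a `rejects` attribute.
#' @export
as_plate_events <- function(x) {
  x <- as_tibble(x)[event_columns()]
  n <- nrow(x)
  dates <- suppressWarnings(as.Date(as.character(x$date)))
  reason <- rep(NA_character_, n)
  check <- function(bad, why) ifelse(is.na(reason) & bad, why, reason)
  reason <- check(!x$plate_type %in% plate_types() | is.na(x$plate_type), "plate_type")
  reason <- check(is.na(x$serving_weight_g) | x$serving_weight_g <= 0, "serving_weight")
  reason <- check(is.na(x$price) | x$price < 0, "price")
  reason <- check(!x$meal_slot %in% meal_slots() | is.na(x$meal_slot), "meal_slot")
  reason <- check(is.na(dates), "date")

  bad <- !is.na(reason)
  rejects <- tibble(row = which(bad), reason = reason[bad])
  if (n > 0 && nrow(rejects) > n / 2) {
    abort(paste0(nrow(rejects), " of ", n, " rows rejected; ",
                 "this looks like a schema mismatch, not corruption"),
          class = "dietledger_parse_error")
  }
  out <- x[!bad, , drop = FALSE]
  out$dish_name <- normalize_food_name(out$dish_name)
  out$plate_type <- as.integer(out$plate_type)
  out$date <- as.Date(as.character(out$date))
  structure(out, rejects = rejects, class = c("plate_events", class(out)))
}

#' Rejected rows of a parsed event file
#'
#' @param events A `plate_events` tibble.
#' @return Tibble with columns `row` (input row number) and `reason`.
#' @export
event_rejects <- function(events) {
  attr(events, "rejects") %||% tibble(row = integer(), reason = character())
}

#' Classify clock times into meal slots
#'
#' Convenience for inputs that carry a timestamp instead of a categorical
#' meal slot: a configurable window classifier, defaulting to lunch =
#' 11:00-14:00 and breakfast = 06:00-10:00, with 17:00-21:00 as supper;
#' times outside every window return `NA`.
#'
#' @param time Times as "HH:MM" strings.
#' @param windows Named list of `c(start_hour, end_hour)` half-open hour
#'   windows `[start, end)`.
#' @return Character vector of meal slots (or `NA`).
#' @export
classify_meal_slot <- function(time,
                               windows = list(breakfast = c(6, 10),
                                              lunch = c(11, 14),
                                              supper = c(17, 21))) {
  parts <- strsplit(as.character(time), ":", fixed = TRUE)
  hours <- purrr::map_dbl(parts, function(p) {
    as.numeric(p[1]) + as.numeric(p[2]) / 60
  })
  out <- rep(NA_character_, length(hours))
  for (slot in names(windows)) {
    w <- windows[[slot]]
    out[!is.na(hours) & hours >= w[1] & hours < w[2]] <- slot
  }
  out
}

# Selection --------------------------------------------------------------------

filter_stage_names <- function() {
  c("lunchtime", "rfid_plate", "recipe_known", "ingredients_covered")
}

#' Apply the four-stage record selection procedure
#'
#' Filters a plate-event stream down to the records suitable for nutrient
#' analysis, applying the stages in a fixed order and reporting the record
#' counts entering and surviving each stage:
#'
#' 1. `lunchtime` — meal slot equals `meal` (default `"lunch"`);
#' 2. `rfid_plate` — plate type is a valid RFID plate code (1, 2 or 3);
#' 3. `recipe_known` — dish name resolves in the recipe database;
#' 4. `ingredients_covered` — the dish's recipe passes
#'    [validate_recipe_coverage()] against the composition table.
#'
#' Event order is preserved. Filtering is total: no errors, every record
#' either survives or is dropped at exactly one stage.
#'
#' @param events A `plate_events` tibble (or plain data frame with the
#'   event columns).
#' @param recipes A `recipe_db` tibble.
#' @param table A `food_composition` tibble.
#' @param meal Meal slot to keep. Default `"lunch"`.
#' @param include_auxiliary Passed to [validate_recipe_coverage()] at
#'   stage 4.
#' @return An object of class `selection_result`: a list with `events`
#'   (surviving `plate_events`, input order preserved) and `report` (a
#'   `filter_report` tibble: `stage`, `entering`, `surviving`). The report
#'   chain is consistent: `surviving` at stage *k* equals `entering` at
#'   stage *k + 1*, and counts never increase.
#' @seealso [tidy.selection_result()], [glance.selection_result()]
#' @export
apply_selection_filters <- function(events, recipes, table, meal = "lunch",
                                    include_auxiliary = FALSE) {
  meal <- match.arg(meal, meal_slots())
  x <- as_tibble(events)
  x$dish_name <- normalize_food_name(x$dish_name)

  keep_fns <- list(
    lunchtime = function(e) e$meal_slot == meal & !is.na(e$meal_slot),
    rfid_plate = function(e) e$plate_type %in% plate_types(),
    recipe_known = function(e) e$dish_name %in% recipes$dish,
    ingredients_covered = function(e) {
      cov <- coverage_report(recipes, table, include_auxiliary)
      e$dish_name %in% cov$dish[cov$covered]
    }
  )

  entering <- integer(0)
  surviving <- integer(0)
  for (stage in filter_stage_names()) {
    entering <- c(entering, nrow(x))
    x <- x[keep_fns[[stage]](x), , drop = FALSE]
    surviving <- c(surviving, nrow(x))
  }
  report <- structure(
    tibble(stage = filter_stage_names(), entering = entering,
           surviving = surviving),
    class = c("filter_report", "tbl_df", "tbl", "data.frame")
  )
  structure(
    list(events = structure(x, class = unique(c("plate_events", class(x)))),
         report = report),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat("Record selection:", x$report$entering[1], "events in,",
      x$report$surviving[nrow(x$report)], "surviving\n")
  print(x$report)
  invisible(x)
}

#' Tidy a selection result into its stage-by-stage filter report
#'
#' @param x A `selection_result` from [apply_selection_filters()].
#' @param ... Unused.
#' @return Tibble with columns `stage`, `entering`, `surviving`, `dropped`.
#' @export
tidy.selection_result <- function(x, ...) {
  mutate(x$report, dropped = .data$entering - .data$surviving)
}

#' One-row summary of a selection result
#'
#' @param x A `selection_result`.
#' @param ... Unused.
#' @return One-row tibble: `n_input`, `n_selected`, `n_dropped`,
#'   `selection_rate`.
#' @export
glance.selection_result <- function(x, ...) {
  n_in <- x$report$entering[1]
  n_out <- x$report$surviving[nrow(x$report)]
  tibble(
    n_input = n_in, n_selected = n_out, n_dropped = n_in - n_out,
    selection_rate = if (n_in > 0) n_out / n_in else NA_real_
  )
}
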