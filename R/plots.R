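# ggplot2 convenience layers for the report objects. Figures are a
# presentation aid; the tabular objects are the contract.

#' Bar chart of a distribution report
#'
#' @param object A `distribution_report`.
#' @param ... Unused.
#' @return A ggplot object: counts by label, percentage printed on the bar.
#' @export
autoplot.distribution_report <- function(object, ...) {
  df <- as_tibble(object)
  df$label <- factor(df$label, levels = rev(df$label))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$count, y = .data$label)) +
    ggplot2::geom_col(fill = "#4477aa") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f%%", .data$percentage)),
                       hjust = -0.1, size = 3) +
    ggplot2::scale_x_continuous(expand = ggplot2::expansion(mult = c(0, 0.15))) +
    ggplot2::labs(x = "count", y = NULL,
                  title = attr(object, "denominator")) +
    ggplot2::theme_minimal()
}

#' Daily intake curves for an intake series
#'
#' Energy on its own panel (kcal), macronutrients (g) on a shared panel —
#' the individual-level "proxy indicator of dietary intake" view.
#'
#' @param object An `intake_series` aggregated by `consumer_date` or
#'   `population_date`.
#' @param nutrients Nutrient columns to draw. Default the core set.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.intake_series <- function(object, nutrients = core_nutrients(), ...) {
  df <- as_tibble(object)
  if (!"date" %in% names(df)) {
    abort("intake series must be aggregated by date to plot a time course",
          class = "dietledger_validation_error")
  }
  nutrients <- intersect(nutrients, names(df))
  long <- tidyr::pivot_longer(df, all_of(nutrients),
                              names_to = "nutrient", values_to = "amount")
  long$panel <- ifelse(long$nutrient == "energy_kcal",
                       "energy (kcal)", "nutrients (g)")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$date, y = .data$amount,
                                     colour = .data$nutrient)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~panel, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = NULL, y = "intake per day", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of a food-frequency table
#'
#' @param object A `frequency_table` from [food_frequency()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.frequency_table <- function(object, ...) {
  df <- as_tibble(object)
  df$dish_name <- factor(df$dish_name, levels = rev(df$dish_name))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$times_chosen, y = .data$dish_name)) +
    ggplot2::geom_col(fill = "#66aa55") +
    ggplot2::labs(x = "times chosen", y = NULL,
                  title = paste("food frequency:", attr(object, "consumer_id"))) +
    ggplot2::theme_minimal()
}

#' One-row summary of a deviation report
#'
#' @param x A `deviation_report`.
#' @param ... Unused.
#' @return One-row tibble: number of compared cells, defined cells, mean
#'   and max MAPD over defined cells.
#' @export
glance.deviation_report <- function(x, ...) {
  tibble(
    n_cells = nrow(x),
    n_defined = sum(!is.na(x$mapd)),
    mean_mapd = mean(x$mapd, na.rm = TRUE),
    max_mapd = max(x$mapd, na.rm = TRUE)
  )
}
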