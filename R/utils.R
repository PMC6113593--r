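# Shared helpers: name normalization and display rounding.

#' Normalize a food name
#'
#' Trims leading/trailing whitespace, collapses internal whitespace runs to a
#' single space and case-folds to lower case. All dish and ingredient lookups
#' in the package key on normalized names; matching is exact after
#' normalization (no fuzzy matching).
#'
#' @param x Character vector of names.
#' @return Character vector of normalized names. Idempotent:
#'   `normalize_food_name(normalize_food_name(x))` equals
#'   `normalize_food_name(x)`.
#' @export
#' @examples
#' normalize_food_name("  Roast   Lamb ")
normalize_food_name <- function(x) {
  x <- trimws(as.character(x))
  x <- gsub("\\s+", " ", x)
  tolower(x)
}

#' Round half away from zero
#'
#' Display rounding used for report percentages (1 decimal) and MAPD values
#' (2 decimals). Unlike [round()], which rounds half to even, ties are rounded
#' away from zero so that printed values match conventional table formatting.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector; `NA` passes through.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

# is_scalar helpers kept internal; rlang has equivalents but these read better
# in validation code.
is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)
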