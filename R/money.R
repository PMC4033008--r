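#' Construct a cost-effectiveness ratio tagged with its economic basis
#'
#' A `money_per_outcome` is an incremental cost-effectiveness (or
#' cost-utility) ratio together with the currency and price year in which
#' it was reported and the outcome unit of its denominator. Carrying the
#' basis on the value is what makes deflation and purchasing-power-parity
#' conversion type-safe: [deflate()] and [ppp_convert()] refuse to operate
#' when the required index entries are missing.
#'
#' @param amount Ratio value in `currency` units per outcome unit. May be
#'   negative: a dominant intervention (cheaper *and* more effective than
#'   its comparator) has a negative ICER.
#' @param currency ISO-4217-style three-letter currency code (e.g. `"CHF"`,
#'   `"GBP"`). Lower case is accepted and normalized.
#' @param price_year Calendar year of the cost data.
#' @param outcome_unit One of `"QALY"` (quality-adjusted life year), `"LY"`
#'   (life year gained) or `"MLY"` (monosymptomatic life year). Common
#'   reporting suffixes such as `"/LYG"` or `"/QALY"` are normalized.
#' @param year_bounds Admissible `price_year` range, as a length-2 integer
#'   vector. The default covers the study scope; widen it for other uses.
#'
#' @return An object of class `money_per_outcome`: a list with fields
#'   `amount`, `currency`, `price_year`, `outcome_unit`.
#' @examples
#' money_per_outcome(55927, "AUD", 2004, "/LYG")
#' @export
money_per_outcome <- function(amount, currency, price_year, outcome_unit,
                              year_bounds = c(1990L, 2015L)) {
  if (!is.numeric(amount) || length(amount) != 1L || !is.finite(amount)) {
    rlang::abort("`amount` must be a single finite number.",
                 class = "drugwelfare_type_error")
  }
  currency <- normalize_currency(currency)
  outcome_unit <- normalize_outcome_unit(outcome_unit)
  price_year <- as.integer(price_year)
  if (is.na(price_year) || price_year < year_bounds[1] ||
      price_year > year_bounds[2]) {
    rlang::abort(
      sprintf("`price_year` must lie in [%d, %d], got %s.",
              year_bounds[1], year_bounds[2], price_year),
      class = "drugwelfare_type_error")
  }
  structure(
    list(amount = as.numeric(amount), currency = currency,
         price_year = price_year, outcome_unit = outcome_unit),
    class = "money_per_outcome")
}

#' @export
print.money_per_outcome <- function(x, ...) {
  cat(sprintf("<money_per_outcome> %s %s/%s (price year %d)\n",
              format(x$amount, big.mark = ","), x$currency, x$outcome_unit,
              x$price_year))
  invisible(x)
}

outcome_units <- c("QALY", "LY", "MLY")

# "/LYG", "LYG", "ly" and friends all mean life years gained; the unit
# lives in the type, never as a suffix on the amount.
normalize_outcome_unit <- function(x) {
  u <- toupper(trimws(sub("^/", "", as.character(x))))
  u[u == "LYG"] <- "LY"
  bad <- !(u %in% outcome_units)
  if (any(bad)) {
    rlang::abort(
      sprintf("Unknown outcome unit(s): %s (expected QALY, LY/LYG or MLY).",
              paste(unique(x[bad]), collapse = ", ")),
      class = "drugwelfare_type_error")
  }
  u
}

normalize_currency <- function(x) {
  cc <- toupper(trimws(as.character(x)))
  bad <- !grepl("^[A-Z]{3}$", cc)
  if (any(bad)) {
    rlang::abort(
      sprintf("Invalid currency code(s): %s (expected a three-letter code).",
              paste(unique(x[bad]), collapse = ", ")),
      class = "drugwelfare_type_error")
  }
  cc
}
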