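#' Restate a ratio to the target year with the GDP deflator
#'
#' Multiplies the amount by the ratio of the source country's GDP-deflator
#' index at the target year to the index at the price year, leaving the
#' currency unchanged. The deflator base year is irrelevant (only the
#' within-currency index ratio enters), indices are annual and never
#' interpolated, and the sign of the amount is preserved — a dominant
#' (negative) ratio stays dominant.
#'
#' @param ratio A [money_per_outcome()].
#' @param tables An [adjustment_tables()].
#' @return A [money_per_outcome()] with `price_year` set to the target
#'   year.
#' @examples
#' tab <- adjustment_tables(
#'   deflator = data.frame(currency = "GBP", year = c(2004, 2010),
#'                         value = c(95, 104.5)),
#'   ppp = data.frame(currency = "GBP", year = 2010, value = 2))
#' deflate(money_per_outcome(100, "GBP", 2004, "QALY"), tab)$amount  # 110
#' @export
deflate <- function(ratio, tables) {
  stopifnot(inherits(ratio, "money_per_outcome"),
            inherits(tables, "adjustment_tables"))
  if (ratio$price_year == tables$target_year) {
    return(ratio)
  }
  from <- deflator_at(tables, ratio$currency, ratio$price_year)
  to <- deflator_at(tables, ratio$currency, tables$target_year)
  out <- ratio
  out$amount <- ratio$amount * to / from
  out$price_year <- tables$target_year
  out
}

#' Convert a target-year ratio into the target currency via PPP
#'
#' Applies the purchasing-power-parity rate (target-currency units per
#' source-currency unit) at the target year. PPP rates, not market
#' exchange rates, are the standard instrument for transferring costs
#' between health systems. The input must already be at target-year
#' prices (run [deflate()] first); a ratio already in the target currency
#' passes through unchanged.
#'
#' @inheritParams deflate
#' @return A [money_per_outcome()] in the target currency.
#' @export
ppp_convert <- function(ratio, tables) {
  stopifnot(inherits(ratio, "money_per_outcome"),
            inherits(tables, "adjustment_tables"))
  if (ratio$price_year != tables$target_year) {
    rlang::abort(
      sprintf("Ratio is at %d prices; deflate to %d before PPP conversion.",
              ratio$price_year, tables$target_year),
      class = "drugwelfare_sequence_error")
  }
  if (ratio$currency == tables$target_currency) {
    return(ratio)
  }
  rate <- ppp_at(tables, ratio$currency, tables$target_year)
  out <- ratio
  out$amount <- ratio$amount * rate
  out$currency <- tables$target_currency
  out
}

#' Harmonize a ratio to the target country-year
#'
#' The two-step transfer: first restate the ratio to target-year prices
#' *within the source country* with the GDP deflator, then convert across
#' currencies with the target-year PPP rate. The order matters whenever
#' the two currency areas inflated at different rates; this function is
#' pinned to deflate-then-convert, so the cross-currency step always
#' happens at target-year price levels. The composition is linear in the
#' amount and preserves its sign.
#'
#' @inheritParams deflate
#' @return A [money_per_outcome()] in the target currency at the target
#'   year.
#' @export
adjust_ratio <- function(ratio, tables) {
  ppp_convert(deflate(ratio, tables), tables)
}

#' Harmonize every ratio of a basket
#'
#' Applies [adjust_ratio()] row-wise and fills `ratio_target_amount`.
#' Missing deflator or PPP entries abort with the offending
#' `(currency, year)` cell named.
#'
#' @param basket A basket tibble (see [read_basket()]).
#' @param tables An [adjustment_tables()].
#' @return The basket with `ratio_target_amount` populated.
#' @export
adjust_basket <- function(basket, tables) {
  basket$ratio_target_amount <- purrr::pmap_dbl(
    basket[c("ratio_amount", "ratio_currency", "ratio_price_year",
             "ratio_outcome_unit")],
    function(ratio_amount, ratio_currency, ratio_price_year,
             ratio_outcome_unit) {
      adjust_ratio(
        money_per_outcome(ratio_amount, ratio_currency, ratio_price_year,
                          ratio_outcome_unit),
        tables)$amount
    })
  basket
}

#' Combined adjustment factor implied by a harmonized basket row
#'
#' For a record carrying both the original and the harmonized ratio, the
#' implied combined deflator-and-PPP factor is simply their quotient.
#' This is a diagnostic: published baskets print both columns, and the
#' implied factors are the ground truth any reconstructed adjustment
#' tables must reproduce.
#'
#' @param basket A basket tibble with both `ratio_amount` and
#'   `ratio_target_amount` populated.
#' @return A numeric vector of per-row factors.
#' @export
implied_adjustment_factor <- function(basket) {
  if (any(is.na(basket$ratio_target_amount))) {
    rlang::abort("Every record needs a harmonized ratio; run adjust_basket().",
                 class = "drugwelfare_sequence_error")
  }
  if (any(basket$ratio_amount == 0)) {
    rlang::abort("Implied factor undefined for a zero original amount.",
                 class = "drugwelfare_validation_error")
  }
  basket$ratio_target_amount / basket$ratio_amount
}
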