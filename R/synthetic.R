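#' Specification for a synthetic drug basket
#'
#' Describes the regimes a generated basket must cover. The default
#' ranges span the reference basket's printed columns: harmonized ratios
#' from strong dominance (about -250,000 per QALY) to well above the
#' 100,000 threshold; incremental effects over four orders of magnitude
#' (10^-4 to 7 QALYs), sampled log-uniformly; model horizons from a
#' couple of days (an acute migraine episode) to a lifetime, also
#' log-uniform; user counts from orphan-drug tens to mass-market
#' hundreds of thousands. Distributions are chosen for *coverage* of
#' these regimes, not fitted to any real basket.
#'
#' @param n_drugs Number of records, >= 1.
#' @param ratio_range Interval of harmonized ratios (target currency per
#'   outcome unit).
#' @param delta_effect_range Log-uniform interval of incremental effects
#'   (> 0).
#' @param horizon_range Log-uniform interval of time horizons in years
#'   (> 0; fractions allowed).
#' @param users_range Uniform interval of ground-truth user counts.
#' @param currencies Character vector of source currencies.
#' @param year_range Integer interval of source price years.
#' @param seed Integer seed; the same spec always generates the same
#'   basket.
#' @return A list of class `basket_spec`.
#' @export
basket_spec <- function(n_drugs,
                        ratio_range = c(-250000, 150000),
                        delta_effect_range = c(1e-4, 7),
                        horizon_range = c(0.002, 75),
                        users_range = c(10, 500000),
                        currencies = c("CHF", "GBP", "AUD", "CAD", "USD",
                                       "EUR"),
                        year_range = c(2000L, 2007L),
                        seed = 1L) {
  n_drugs <- as.integer(n_drugs)
  if (is.na(n_drugs) || n_drugs < 1L) {
    rlang::abort("`n_drugs` must be a positive integer.",
                 class = "drugwelfare_spec_error")
  }
  for (rng in list(ratio_range = ratio_range,
                   delta_effect_range = delta_effect_range,
                   horizon_range = horizon_range,
                   users_range = users_range)) {
    if (length(rng) != 2L || !all(is.finite(rng)) || rng[1] >= rng[2]) {
      rlang::abort("Ranges must be non-degenerate (low < high) and finite.",
                   class = "drugwelfare_spec_error")
    }
  }
  if (delta_effect_range[1] <= 0 || horizon_range[1] <= 0 ||
      users_range[1] < 0) {
    rlang::abort("Effects and horizons must be positive; users non-negative.",
                 class = "drugwelfare_spec_error")
  }
  if (length(currencies) == 0) {
    rlang::abort("At least one currency is required.",
                 class = "drugwelfare_spec_error")
  }
  structure(
    list(n_drugs = n_drugs, ratio_range = ratio_range,
         delta_effect_range = delta_effect_range,
         horizon_range = horizon_range, users_range = users_range,
         currencies = normalize_currency(currencies),
         year_range = as.integer(year_range), seed = as.integer(seed)),
    class = "basket_spec")
}

runif_log <- function(n, range) {
  exp(stats::runif(n, log(range[1]), log(range[2])))
}

#' Generate a synthetic basket with known ground truth
#'
#' Samples `spec$n_drugs` records with every field populated, including
#' ground-truth user counts (`user_source = "synthetic"`), so the whole
#' pipeline — harmonization, welfare evaluation, user inversion,
#' sensitivity — can be exercised against known answers. Original-basis
#' ratios are derived from the harmonized ones by dividing out the
#' combined adjustment factor of `tables`, so [adjust_basket()] on the
#' generated basket reproduces `ratio_target_amount` exactly.
#'
#' For baskets of at least 4 drugs whose `ratio_range` spans the
#' corresponding regime, the sample is guaranteed to contain at least
#' one dominant (negative-ratio) drug and at least one drug priced above
#' 100,000 per outcome unit.
#'
#' @param spec A [basket_spec()].
#' @param tables Optional [adjustment_tables()]; generated from the spec
#'   seed when omitted.
#' @return A basket tibble with attribute `tables` (the adjustment
#'   tables used).
#' @examples
#' b <- generate_basket(basket_spec(8, seed = 42))
#' @export
generate_basket <- function(spec, tables = NULL) {
  stopifnot(inherits(spec, "basket_spec"))
  if (is.null(tables)) {
    tables <- generate_adjustment_tables(
      currencies = spec$currencies,
      years = seq(min(spec$year_range), 2010L),
      seed = spec$seed + 1L)
  }
  n <- spec$n_drugs
  basket <- withr::with_seed(spec$seed, {
    ratio_t <- stats::runif(n, spec$ratio_range[1], spec$ratio_range[2])
    # coverage guarantee: pin one draw into each extreme regime when the
    # requested range reaches it
    if (n >= 4L) {
      if (spec$ratio_range[1] < 0 && !any(ratio_t < 0)) {
        ratio_t[1] <- stats::runif(1, spec$ratio_range[1], min(0, spec$ratio_range[2]))
      }
      if (spec$ratio_range[2] > 100000 && !any(ratio_t > 100000)) {
        ratio_t[2] <- stats::runif(1, max(100000, spec$ratio_range[1]),
                                   spec$ratio_range[2])
      }
    }
    delta <- runif_log(n, spec$delta_effect_range)
    horizon <- runif_log(n, spec$horizon_range)
    users <- stats::runif(n, spec$users_range[1], spec$users_range[2])
    currency <- sample(spec$currencies, n, replace = TRUE)
    year <- sample(seq(spec$year_range[1], spec$year_range[2]), n,
                   replace = TRUE)
    unit <- sample(c("QALY", "LY", "MLY"), n, replace = TRUE,
                   prob = c(0.8, 0.15, 0.05))
    tibble::tibble(
      name = sprintf("drug_%03d", seq_len(n)),
      brand = sprintf("Brand%03d", seq_len(n)),
      ratio_amount = NA_real_,
      ratio_currency = currency,
      ratio_price_year = as.integer(year),
      ratio_outcome_unit = unit,
      ratio_target_amount = ratio_t,
      delta_effect = delta,
      time_horizon_years = horizon,
      n_users = users,
      perspective = "synthetic",
      user_source = "synthetic")
  })
  factor <- purrr::map2_dbl(
    basket$ratio_currency, basket$ratio_price_year,
    function(cc, yy) {
      d <- deflator_at(tables, cc, tables$target_year) /
        deflator_at(tables, cc, yy)
      p <- if (cc == tables$target_currency) 1 else
        ppp_at(tables, cc, tables$target_year)
      d * p
    })
  basket$ratio_amount <- basket$ratio_target_amount / factor
  attr(basket, "tables") <- tables
  basket
}

#' Generate complete synthetic adjustment tables
#'
#' Per-currency annual GDP-deflator series with mild inflation (0-5% a
#' year, so indices are monotone non-decreasing in the year) and positive
#' PPP rates into the target currency at the target year. By construction
#' every lookup needed to harmonize a basket drawn over the same
#' currencies and years succeeds, and combined year-to-target factors
#' stay within the 0.8-2.2 band observed across published baskets.
#'
#' @param currencies Character vector of currency codes.
#' @param years Integer years the deflator series must cover (the target
#'   year is always included).
#' @param target_currency,target_year Harmonization target.
#' @param seed Integer seed.
#' @return An [adjustment_tables()] object.
#' @export
generate_adjustment_tables <- function(currencies, years = 2000:2010,
                                       target_currency = "CHF",
                                       target_year = 2010L, seed = 1L) {
  if (length(currencies) == 0) {
    rlang::abort("At least one currency is required.",
                 class = "drugwelfare_spec_error")
  }
  currencies <- unique(normalize_currency(currencies))
  years <- sort(unique(c(as.integer(years), as.integer(target_year))))
  withr::with_seed(seed, {
    defl <- purrr::map_dfr(currencies, function(cc) {
      infl <- stats::runif(length(years) - 1, 0, 0.05)
      idx <- 100 * cumprod(c(1, 1 + infl))
      tibble::tibble(currency = cc, year = years, value = idx)
    })
    ppp <- tibble::tibble(
      currency = currencies,
      year = as.integer(target_year),
      value = ifelse(currencies == target_currency, 1,
                     stats::runif(length(currencies), 0.85, 1.30)))
    adjustment_tables(defl, ppp, target_currency, target_year)
  })
}

#' The bundled 31-drug Swiss 2010 reference basket
#'
#' Returns the package's canonical fixture: the published basket of 31
#' innovative drugs launched from 2000 onward, as evaluated for the
#' Swiss economy in 2010 — drug identity, original-basis ratio, ratio
#' harmonized to CHF 2010, incremental effect, time horizon and
#' perspective — together with the published per-drug welfare column.
#' The welfare column is kept separate from the basket because it is an
#' *output* of the welfare formula, not an input; with user counts
#' confidential, it is also the input from which [populate_users()]
#' back-derives them.
#'
#' Values are stored exactly as printed, including the bosentan welfare
#' figure of 10,717,086 that the source's own prose rounds to
#' 10,717,090 — the fixture is auditable against the table, so the
#' 4-franc discrepancy is preserved, not resolved.
#'
#' @return A list with `basket` (31-row basket tibble, `n_users` absent)
#'   and `welfare` (tibble `name,welfare`, in CHF/year at the 100,000
#'   threshold).
#' @examples
#' fx <- table2_fixture()
#' sum(fx$welfare$welfare)  # 781,388,456 CHF/year
#' @export
table2_fixture <- function() {
  basket <- read_basket(
    system.file("extdata", "table2_basket.csv", package = "drugwelfare",
                mustWork = TRUE))
  welfare <- readr::read_csv(
    system.file("extdata", "table2_welfare.csv", package = "drugwelfare",
                mustWork = TRUE),
    show_col_types = FALSE,
    col_types = readr::cols(name = readr::col_character(),
                            welfare = readr::col_double()))
  list(basket = basket, welfare = welfare)
}
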