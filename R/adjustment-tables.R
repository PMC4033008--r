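#' Economic adjustment tables: GDP deflators and PPP rates
#'
#' Bundles the two index tables needed to transfer a cost-effectiveness
#' ratio to a target country-year: an annual GDP-deflator index per
#' currency area (arbitrary base year; only within-currency ratios are
#' ever used) and purchasing-power-parity rates into the target currency
#' at the target year.
#'
#' Completeness against a particular basket is checked lazily, at
#' adjustment time: a missing `(currency, year)` deflator entry or a
#' missing PPP rate raises a completeness error naming the cell.
#'
#' @param deflator A data frame with columns `currency`, `year`, `value`
#'   (index value, strictly positive).
#' @param ppp A data frame with columns `currency`, `year`, `value`
#'   (target-currency units per source-currency unit, strictly positive).
#' @param target_currency Currency all ratios are converted into.
#' @param target_year Year all ratios are restated to.
#'
#' @return An object of class `adjustment_tables`.
#' @seealso [read_adjustment_tables()], [deflate()], [ppp_convert()]
#' @export
adjustment_tables <- function(deflator, ppp, target_currency = "CHF",
                              target_year = 2010L) {
  deflator <- tibble::as_tibble(deflator)[c("currency", "year", "value")]
  ppp <- tibble::as_tibble(ppp)[c("currency", "year", "value")]
  for (tab in list(deflator = deflator, ppp = ppp)) {
    if (any(!is.finite(tab$value) | tab$value <= 0)) {
      i <- which(!is.finite(tab$value) | tab$value <= 0)[1]
      rlang::abort(
        sprintf("Non-positive index value at (%s, %d).",
                tab$currency[i], tab$year[i]),
        class = "drugwelfare_validation_error")
    }
  }
  deflator$currency <- normalize_currency(deflator$currency)
  ppp$currency <- normalize_currency(ppp$currency)
  structure(
    list(deflator = deflator, ppp = ppp,
         target_currency = normalize_currency(target_currency),
         target_year = as.integer(target_year)),
    class = "adjustment_tables")
}

#' @export
print.adjustment_tables <- function(x, ...) {
  cat(sprintf(
    "<adjustment_tables> target %s %d; deflator: %d entries (%d currencies); ppp: %d entries\n",
    x$target_currency, x$target_year, nrow(x$deflator),
    length(unique(x$deflator$currency)), nrow(x$ppp)))
  invisible(x)
}

deflator_at <- function(tables, currency, year) {
  hit <- tables$deflator$currency == currency & tables$deflator$year == year
  if (!any(hit)) {
    rlang::abort(
      sprintf("No GDP-deflator entry for (%s, %d).", currency, year),
      class = "drugwelfare_completeness_error")
  }
  tables$deflator$value[which(hit)[1]]
}

ppp_at <- function(tables, currency, year) {
  hit <- tables$ppp$currency == currency & tables$ppp$year == year
  if (!any(hit)) {
    rlang::abort(
      sprintf("No PPP rate for (%s, %d).", currency, year),
      class = "drugwelfare_completeness_error")
  }
  tables$ppp$value[which(hit)[1]]
}

#' Read or write adjustment tables in the long CSV format
#'
#' The on-disk format is a long table with columns
#' `table,currency,year,value`, where `table` is `"deflator"` or `"ppp"`.
#' `read_adjustment_tables()` and `write_adjustment_tables()` are inverse
#' up to numeric printing precision (values are written in full double
#' precision, so round trips are exact in practice).
#'
#' @param path Path to a CSV file.
#' @param target_currency,target_year Economic basis every ratio is
#'   harmonized to; stored on the returned object.
#' @return `read_adjustment_tables()` returns an [adjustment_tables()]
#'   object; `write_adjustment_tables()` returns `path` invisibly.
#' @export
read_adjustment_tables <- function(path, target_currency = "CHF",
                                   target_year = 2010L) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("File not found: %s", path),
                 class = "drugwelfare_io_error")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           table = readr::col_character(),
                           currency = readr::col_character(),
                           year = readr::col_integer(),
                           value = readr::col_double()))
  missing_cols <- setdiff(c("table", "currency", "year", "value"), names(raw))
  if (length(missing_cols) > 0) {
    rlang::abort(sprintf("Missing column(s): %s",
                         paste(missing_cols, collapse = ", ")),
                 class = "drugwelfare_schema_error")
  }
  bad <- !(raw$table %in% c("deflator", "ppp"))
  if (any(bad)) {
    rlang::abort(sprintf("Unknown table tag(s): %s",
                         paste(unique(raw$table[bad]), collapse = ", ")),
                 class = "drugwelfare_schema_error")
  }
  adjustment_tables(deflator = raw[raw$table == "deflator", -1],
                    ppp = raw[raw$table == "ppp", -1],
                    target_currency = target_currency,
                    target_year = target_year)
}

#' @param tables An [adjustment_tables()] object.
#' @rdname read_adjustment_tables
#' @export
write_adjustment_tables <- function(tables, path) {
  stopifnot(inherits(tables, "adjustment_tables"))
  long <- dplyr::bind_rows(
    dplyr::mutate(tables$deflator, table = "deflator", .before = 1),
    dplyr::mutate(tables$ppp, table = "ppp", .before = 1))
  readr::write_csv(long, path)
  invisible(path)
}

#' Synthetic adjustment tables bundled with the package
#'
#' The real OECD deflator and PPP series are version-dependent and are not
#' redistributed here; the package ships a synthetic set of smooth annual
#' deflator series (2000-2010) and 2010 PPP rates for the six currencies
#' of the reference basket. The AUD series is calibrated so that the
#' combined 2004-to-2010 adjustment factor reproduces the bosentan row of
#' the reference basket exactly; all other entries are plausible but
#' synthetic, and the per-row implied factors of the reference basket
#' (see [implied_adjustment_factor()]) remain the ground truth.
#'
#' @return An [adjustment_tables()] object.
#' @export
synthetic_adjustment_fixture <- function() {
  read_adjustment_tables(
    system.file("extdata", "adjustment_tables_synthetic.csv",
                package = "drugwelfare", mustWork = TRUE))
}
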