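#' Read a drug basket from CSV
#'
#' A *basket* is the analysis dataset: one row per drug, holding the
#' published cost-effectiveness ratio with its economic basis (currency
#' and price year), the ratio harmonized to the target country-year, the
#' incremental effect per treated patient over the model horizon, the
#' model time horizon, and (optionally) the number of users. Baskets are
#' plain tibbles with the columns listed under *Basket columns*, so all
#' dplyr verbs apply.
#'
#' Rows that violate a structural invariant (non-positive time horizon,
#' zero incremental effect, unknown currency or outcome unit, negative
#' user count, unparseable numeric) are rejected, never silently dropped:
#' the returned tibble carries a `diagnostics` attribute with one row per
#' rejected record (`row`, `field`, `message`), and
#' `nrow(input) == nrow(accepted) + nrow(diagnostics)` always holds.
#'
#' @section Basket columns:
#' `name`, `brand`, `ratio_amount`, `ratio_currency`, `ratio_price_year`,
#' `ratio_outcome_unit`, `ratio_target_amount`, `delta_effect`,
#' `time_horizon_years`, `n_users`, `perspective`, `user_source`.
#' `ratio_target_amount` and `n_users` may be `NA` before
#' [adjust_basket()] / [populate_users()] have run. `perspective` is an
#' uninterpreted provenance tag (the source studies mix societal and
#' payer perspectives); it gates no computation. An absent user count is
#' `NA`, never 0 — zero users is a valid, degenerate count.
#'
#' @param path Path to a CSV file with a header row.
#' @param schema_config Optional named character vector mapping canonical
#'   column names (names) to the column names used in the file (values),
#'   for ingesting baskets with foreign headers.
#' @param year_bounds Admissible price-year range (see
#'   [money_per_outcome()]).
#'
#' @return A tibble of accepted records in file order, with attribute
#'   `diagnostics` (a tibble, zero rows when every record was accepted).
#' @examples
#' fx <- table2_fixture()
#' nrow(fx$basket)  # 31
#' @export
read_basket <- function(path, schema_config = NULL,
                        year_bounds = c(1990L, 2015L)) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("File not found: %s", path),
                 class = "drugwelfare_io_error")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (!is.null(schema_config)) {
    for (canon in names(schema_config)) {
      file_col <- schema_config[[canon]]
      if (!file_col %in% names(raw)) {
        rlang::abort(sprintf("Schema maps `%s` to missing column `%s`.",
                             canon, file_col),
                     class = "drugwelfare_schema_error")
      }
      names(raw)[names(raw) == file_col] <- canon
    }
  }
  missing_cols <- setdiff(basket_columns, names(raw))
  if (length(missing_cols) > 0) {
    rlang::abort(sprintf("Missing required column(s): %s",
                         paste(missing_cols, collapse = ", ")),
                 class = "drugwelfare_schema_error")
  }
  raw <- raw[basket_columns]
  parse_basket_rows(raw, year_bounds = year_bounds)
}

basket_columns <- c("name", "brand", "ratio_amount", "ratio_currency",
                    "ratio_price_year", "ratio_outcome_unit",
                    "ratio_target_amount", "delta_effect",
                    "time_horizon_years", "n_users", "perspective",
                    "user_source")

basket_numeric_columns <- c("ratio_amount", "ratio_price_year",
                            "ratio_target_amount", "delta_effect",
                            "time_horizon_years", "n_users")

user_sources <- c("manufacturer_potential", "insurer_actual",
                  "packages_derived", "inverted", "synthetic")

parse_basket_rows <- function(raw, year_bounds) {
  n <- nrow(raw)
  diags <- list()
  note <- function(row, field, message) {
    diags[[length(diags) + 1L]] <<- tibble::tibble(
      row = row, field = field, message = message)
  }
  recs <- vector("list", n)
  for (i in seq_len(n)) {
    rec <- as.list(raw[i, ])
    ok <- TRUE
    for (col in basket_numeric_columns) {
      val <- rec[[col]]
      if (is.na(val) || val == "") {
        rec[[col]] <- NA_real_
        next
      }
      num <- suppressWarnings(as.numeric(val))
      if (is.na(num)) {
        # one diagnostic per rejected row keeps rows-in = accepted + rejected
        note(i, col, sprintf("unparseable numeric: '%s'", val))
        ok <- FALSE
        break
      }
      rec[[col]] <- num
    }
    if (!ok) next
    chk <- tryCatch({
      rec$ratio_currency <- normalize_currency(rec$ratio_currency)
      rec$ratio_outcome_unit <- normalize_outcome_unit(rec$ratio_outcome_unit)
      TRUE
    }, drugwelfare_type_error = function(e) {
      note(i, "ratio_currency/ratio_outcome_unit", conditionMessage(e))
      FALSE
    })
    if (!chk) next
    if (is.na(rec$ratio_price_year) ||
        rec$ratio_price_year < year_bounds[1] ||
        rec$ratio_price_year > year_bounds[2]) {
      note(i, "ratio_price_year",
           sprintf("price year outside [%d, %d]", year_bounds[1], year_bounds[2]))
      next
    }
    if (is.na(rec$time_horizon_years) || rec$time_horizon_years <= 0) {
      note(i, "time_horizon_years", "time horizon must be > 0")
      next
    }
    if (is.na(rec$delta_effect) || rec$delta_effect == 0) {
      note(i, "delta_effect", "incremental effect must be nonzero")
      next
    }
    if (!is.na(rec$n_users) && rec$n_users < 0) {
      note(i, "n_users", "user count must be >= 0 (absent = empty cell)")
      next
    }
    if (!is.na(rec$user_source) && rec$user_source != "" &&
        !rec$user_source %in% user_sources) {
      note(i, "user_source",
           sprintf("unknown user_source '%s' (expected one of %s)",
                   rec$user_source, paste(user_sources, collapse = ", ")))
      next
    }
    if (is.na(rec$user_source) || rec$user_source == "") {
      rec$user_source <- NA_character_
    }
    rec$ratio_price_year <- as.integer(rec$ratio_price_year)
    recs[[i]] <- tibble::as_tibble(rec)
  }
  accepted <- dplyr::bind_rows(recs[!vapply(recs, is.null, logical(1))])
  if (nrow(accepted) == 0) {
    accepted <- empty_basket()
  }
  diagnostics <- if (length(diags) > 0) dplyr::bind_rows(diags) else
    tibble::tibble(row = integer(), field = character(), message = character())
  if (nrow(diagnostics) > 0) {
    rlang::warn(sprintf("%d basket row(s) rejected; see attr(x, 'diagnostics').",
                        nrow(diagnostics)))
  }
  attr(accepted, "diagnostics") <- diagnostics
  accepted
}

empty_basket <- function() {
  tibble::tibble(
    name = character(), brand = character(), ratio_amount = numeric(),
    ratio_currency = character(), ratio_price_year = integer(),
    ratio_outcome_unit = character(), ratio_target_amount = numeric(),
    delta_effect = numeric(), time_horizon_years = numeric(),
    n_users = numeric(), perspective = character(),
    user_source = character())
}

#' Write a drug basket to CSV
#'
#' Inverse of [read_basket()]: money columns are written to 2 decimal
#' places, all other numerics in full precision, and empty cells encode
#' missing values. `read_basket(write_basket(b))` recovers `b` up to that
#' serialization precision.
#'
#' @param basket A basket tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_basket <- function(basket, path) {
  out <- basket[basket_columns]
  out$ratio_amount <- round(out$ratio_amount, 2)
  out$ratio_target_amount <- round(out$ratio_target_amount, 2)
  readr::write_csv(out, path, na = "")
  invisible(path)
}
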