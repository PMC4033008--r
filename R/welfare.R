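#' Per-drug annual welfare impact at a QALY threshold
#'
#' For each drug the welfare impact is the annualized, population-scaled
#' net monetary benefit at the stated willingness-to-pay threshold
#' \eqn{\lambda}:
#' \deqn{W = (\lambda - ICER) \times \Delta E / T \times n}
#' where \eqn{ICER} is the harmonized cost-effectiveness ratio (target
#' currency per outcome unit), \eqn{\Delta E} the incremental effect per
#' treated patient over the model horizon, \eqn{T} the time horizon in
#' years (so \eqn{\Delta E / T} is the effect gained per user-year), and
#' \eqn{n} the number of users.
#'
#' A dominant drug (negative ratio) needs no special case: plain signed
#' arithmetic turns \eqn{\lambda - ICER} into \eqn{\lambda + |ICER|},
#' i.e. a larger per-user benefit, which is exactly the intended
#' semantics. Effects measured in life years (LY) or monosymptomatic life
#' years (MLY) are valued at the QALY threshold — the convention of the
#' underlying welfare framework — but such rows are flagged with
#' `outcome_unit_caveat = TRUE`, since an LY is worth at most one QALY
#' and the result may overstate the gain.
#'
#' Records with negative incremental effect are evaluated as-is (the
#' formula is signed throughout) but trigger a basket-level warning: the
#' sign of an ICER alone does not identify the quadrant of the
#' cost-effectiveness plane.
#'
#' All money is carried in full double precision; rounding is a
#' reporting concern (see [write_results()]).
#'
#' @param basket A basket tibble with `ratio_target_amount` and `n_users`
#'   populated (see [adjust_basket()] and [populate_users()]).
#' @param threshold Willingness-to-pay per QALY in target-currency units;
#'   defaults to 100,000.
#' @return A tibble with one row per drug: `name`, `threshold`,
#'   `adjusted_ratio`, `annual_effect` (= `delta_effect /
#'   time_horizon_years`), `n_users`, `welfare` (target-currency units
#'   per year) and `outcome_unit_caveat`.
#' @examples
#' fx <- table2_fixture()
#' basket <- populate_users(fx$basket, welfare = fx$welfare)
#' welfare_impact(basket)
#' @export
welfare_impact <- function(basket, threshold = 100000) {
  check_evaluable(basket)
  if (any(basket$delta_effect < 0)) {
    rlang::warn(paste0(
      "Basket contains negative incremental effects; an ICER's sign is ",
      "ambiguous without quadrant information."))
  }
  annual_effect <- basket$delta_effect / basket$time_horizon_years
  tibble::tibble(
    name = basket$name,
    threshold = threshold,
    adjusted_ratio = basket$ratio_target_amount,
    annual_effect = annual_effect,
    n_users = basket$n_users,
    welfare = (threshold - basket$ratio_target_amount) * annual_effect *
      basket$n_users,
    outcome_unit_caveat = basket$ratio_outcome_unit != "QALY")
}

check_evaluable <- function(basket) {
  if (nrow(basket) == 0) {
    return(invisible(basket))
  }
  if (any(is.na(basket$ratio_target_amount))) {
    bad <- basket$name[is.na(basket$ratio_target_amount)][1]
    rlang::abort(
      sprintf("'%s' has no harmonized ratio; run adjust_basket() first.", bad),
      class = "drugwelfare_sequence_error")
  }
  if (any(is.na(basket$n_users))) {
    bad <- basket$name[is.na(basket$n_users)][1]
    rlang::abort(
      sprintf("'%s' has no user count; run populate_users() first.", bad),
      class = "drugwelfare_sequence_error")
  }
  invisible(basket)
}

#' Aggregate annual welfare impact of a basket
#'
#' Sums the per-drug welfare impacts and also reports the basket's
#' aggregate slope \eqn{\Sigma k = \Sigma (\Delta E / T \times n)}
#' (QALYs per year across all users), which makes the total an affine
#' function of the threshold: \eqn{W(\lambda) = \lambda \Sigma k -
#' \Sigma c k}. The closed form is what [welfare_at_thresholds()]
#' exploits.
#'
#' @inheritParams welfare_impact
#' @return A list of class `welfare_total`: `total` (currency/year),
#'   `slope` (QALYs/year), `intercept` (`total - threshold * slope`),
#'   `threshold`, `n_drugs`, and the `per_drug` tibble from
#'   [welfare_impact()]. An empty basket totals 0.
#' @export
total_welfare <- function(basket, threshold = 100000) {
  per_drug <- welfare_impact(basket, threshold)
  slope <- sum(per_drug$annual_effect * per_drug$n_users)
  total <- sum(per_drug$welfare)
  structure(
    list(total = total, slope = slope,
         intercept = total - threshold * slope,
         threshold = threshold, n_drugs = nrow(per_drug),
         per_drug = per_drug),
    class = "welfare_total")
}

#' @export
print.welfare_total <- function(x, ...) {
  cat(sprintf(
    "<welfare_total> %d drugs at threshold %s: total %.2f million/year (slope %.4g QALYs/year)\n",
    x$n_drugs, format(x$threshold, big.mark = ",", scientific = FALSE),
    x$total / 1e6, x$slope))
  invisible(x)
}

#' Basket totals across several QALY thresholds
#'
#' Because the total is affine in the threshold, totals at any set of
#' thresholds follow from one per-drug evaluation:
#' \eqn{W(\lambda_2) - W(\lambda_1) = (\lambda_2 - \lambda_1) \Sigma k}
#' holds exactly, by construction.
#'
#' @inheritParams welfare_impact
#' @param thresholds Numeric vector of willingness-to-pay values.
#' @param base_threshold Threshold at which the basket is evaluated once
#'   to obtain slope and intercept.
#' @return A tibble with columns `threshold` and `total`.
#' @export
welfare_at_thresholds <- function(basket, thresholds,
                                  base_threshold = 100000) {
  base <- total_welfare(basket, base_threshold)
  tibble::tibble(
    threshold = as.numeric(thresholds),
    total = base$intercept + as.numeric(thresholds) * base$slope)
}

#' Write a welfare report to CSV
#'
#' One row per drug with columns
#' `name,threshold,adjusted_ratio,annual_effect,n_users,welfare`, followed
#' by a final `TOTAL` row (and, optionally, a `SLOPE` row carrying the
#' aggregate QALYs/year in the `annual_effect` column). Money columns are
#' written to 2 decimal places; [read_results()] recovers the report to
#' that precision.
#'
#' @param results The `per_drug` tibble of a [total_welfare()] result, or
#'   a `welfare_total` itself.
#' @param path Output CSV path.
#' @param include_slope Append the `SLOPE` row.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, include_slope = FALSE) {
  if (inherits(results, "welfare_total")) {
    results <- results$per_drug
  }
  if (nrow(results) == 0) {
    rlang::abort("Nothing to write: empty results.",
                 class = "drugwelfare_validation_error")
  }
  cols <- c("name", "threshold", "adjusted_ratio", "annual_effect",
            "n_users", "welfare")
  out <- results[cols]
  slope <- sum(out$annual_effect * out$n_users)
  total_row <- tibble::tibble(
    name = "TOTAL", threshold = out$threshold[1], adjusted_ratio = NA_real_,
    annual_effect = NA_real_, n_users = NA_real_,
    welfare = sum(out$welfare))
  if (include_slope) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      name = "SLOPE", threshold = out$threshold[1],
      adjusted_ratio = NA_real_, annual_effect = slope,
      n_users = NA_real_, welfare = NA_real_))
  }
  out <- dplyr::bind_rows(out, total_row)
  out$adjusted_ratio <- round(out$adjusted_ratio, 2)
  out$welfare <- sprintf("%.2f", out$welfare)
  out$welfare[out$welfare == "NA"] <- ""
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' @rdname write_results
#' @return `read_results()` returns a list with `per_drug` (drug rows) and
#'   `total` (the `TOTAL` row's welfare).
#' @export
read_results <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           name = readr::col_character(),
                           .default = readr::col_double()))
  list(per_drug = raw[!raw$name %in% c("TOTAL", "SLOPE"), ],
       total = raw$welfare[raw$name == "TOTAL"][1])
}
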