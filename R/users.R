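#' Invert the welfare formula for the number of users
#'
#' National user counts behind published welfare figures are often
#' confidential. Since the welfare impact is linear in the user count,
#' a known per-drug welfare value determines it exactly:
#' \deqn{n = W / ((\lambda - ICER) \times \Delta E / T)}
#' Forward evaluation with the inverted count reproduces the welfare
#' value to floating-point precision.
#'
#' Inverted counts are deliberately *not* rounded to whole persons:
#' printed welfare figures generally imply fractional counts, and
#' rounding would break downstream reproduction of threshold and
#' sensitivity totals. Round at reporting time if a head count is wanted.
#'
#' @param basket A basket tibble with `ratio_target_amount` populated.
#' @param welfare Per-drug annual welfare values (currency/year), recycled
#'   against the basket rows.
#' @param threshold Willingness-to-pay per QALY used when the welfare
#'   values were computed.
#' @return Numeric vector of user counts, one per row. A zero welfare
#'   with nonzero per-user benefit gives 0 users. A zero per-user net
#'   benefit (threshold equal to the ratio, or zero effect) has no unique
#'   solution and is an error; a negative count is returned but flagged
#'   with a warning, as it signals inconsistent inputs.
#' @examples
#' fx <- table2_fixture()
#' users <- invert_users(fx$basket, fx$welfare$welfare)
#' @export
invert_users <- function(basket, welfare, threshold = 100000) {
  if (any(is.na(basket$ratio_target_amount))) {
    rlang::abort("Harmonized ratios required; run adjust_basket() first.",
                 class = "drugwelfare_sequence_error")
  }
  welfare <- rep_len(as.numeric(welfare), nrow(basket))
  per_user <- (threshold - basket$ratio_target_amount) *
    basket$delta_effect / basket$time_horizon_years
  degenerate <- per_user == 0
  if (any(degenerate)) {
    rlang::abort(
      sprintf("Zero net benefit per user for '%s': no unique user count.",
              basket$name[degenerate][1]),
      class = "drugwelfare_no_unique_solution_error")
  }
  users <- welfare / per_user
  if (any(users < 0)) {
    rlang::warn(sprintf(
      "Negative user count for %s: welfare and per-user benefit disagree in sign.",
      paste(basket$name[users < 0], collapse = ", ")))
  }
  users
}

#' Estimate users from package-sales figures
#'
#' When neither manufacturer nor insurer counts are available, annual
#' sales volumes give an indirect estimate: the doses sold in a year
#' divided by the doses one patient consumes in a year,
#' `packages_sold * doses_per_package / (usual_daily_dose *
#' treatment_days_per_year)`. The estimate is invariant to re-expressing
#' the dose (halving the package size while doubling the package count
#' changes nothing).
#'
#' @param packages_sold Packages sold per year.
#' @param doses_per_package Doses per package.
#' @param usual_daily_dose Doses per treatment day.
#' @param treatment_days_per_year Treatment days per year. Defaults to
#'   365, the chronic-therapy case; episodic therapies must state their
#'   own exposure.
#' @return Estimated number of users (real, not rounded).
#' @examples
#' users_from_packages(3650, 100, 1)  # 1000
#' @export
users_from_packages <- function(packages_sold, doses_per_package,
                                usual_daily_dose,
                                treatment_days_per_year = 365) {
  args <- list(packages_sold = packages_sold,
               doses_per_package = doses_per_package,
               usual_daily_dose = usual_daily_dose,
               treatment_days_per_year = treatment_days_per_year)
  for (nm in names(args)) {
    if (any(!is.finite(args[[nm]]) | args[[nm]] <= 0)) {
      rlang::abort(sprintf("`%s` must be > 0.", nm),
                   class = "drugwelfare_validation_error")
    }
  }
  packages_sold * doses_per_package /
    (usual_daily_dose * treatment_days_per_year)
}

#' Fill in the user count of every basket record
#'
#' Resolves `n_users` for each drug from the best available source, in
#' fixed precedence: an explicit count on the record wins; otherwise a
#' matching row in the package-sales table ([users_from_packages()]);
#' otherwise exact inversion from a supplied per-drug welfare value
#' ([invert_users()]). `user_source` records which route was taken. A
#' drug with none of the three is an error naming the drug.
#'
#' @param basket A basket tibble with `ratio_target_amount` populated.
#' @param welfare Optional per-drug welfare values: a data frame with
#'   columns `name` and `welfare` (matched by name) or a numeric vector
#'   in basket order.
#' @param packages Optional package-sales table with columns
#'   `name,packages_sold,doses_per_package,usual_daily_dose,
#'   treatment_days_per_year` (matched by name).
#' @param threshold Threshold behind the supplied welfare values.
#' @return The basket with `n_users` populated and `user_source` set to
#'   the provenance of each count.
#' @export
populate_users <- function(basket, welfare = NULL, packages = NULL,
                           threshold = 100000) {
  out <- basket
  welfare_vec <- rep(NA_real_, nrow(out))
  if (!is.null(welfare)) {
    if (is.data.frame(welfare)) {
      welfare_vec <- welfare$welfare[match(out$name, welfare$name)]
    } else {
      welfare_vec <- rep_len(as.numeric(welfare), nrow(out))
    }
  }
  for (i in seq_len(nrow(out))) {
    if (!is.na(out$n_users[i])) {
      if (is.na(out$user_source[i])) {
        out$user_source[i] <- "insurer_actual"
      }
      next
    }
    pkg_row <- if (!is.null(packages)) match(out$name[i], packages$name)
      else NA_integer_
    if (!is.na(pkg_row)) {
      days <- if ("treatment_days_per_year" %in% names(packages))
        packages$treatment_days_per_year[pkg_row] else NA_real_
      if (is.na(days)) days <- 365
      out$n_users[i] <- users_from_packages(
        packages$packages_sold[pkg_row],
        packages$doses_per_package[pkg_row],
        packages$usual_daily_dose[pkg_row],
        days)
      out$user_source[i] <- "packages_derived"
      next
    }
    if (!is.na(welfare_vec[i])) {
      out$n_users[i] <- invert_users(out[i, ], welfare_vec[i], threshold)
      out$user_source[i] <- "inverted"
      next
    }
    rlang::abort(
      sprintf("Cannot resolve users for '%s': no explicit count, no sales record, no welfare value.",
              out$name[i]),
      class = "drugwelfare_unresolved_users_error")
  }
  out
}
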