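record_parameters <- c("n_users", "adjusted_ratio", "delta_effect",
                       "time_horizon")

#' Scale one parameter class across an entire basket
#'
#' Returns a copy of the basket with the named field multiplied by
#' `factor` on every record, all other fields untouched. This is the
#' one-way perturbation of a univariate sensitivity analysis applied at
#' the parameter-class level (all drugs at once), not a per-drug bar.
#'
#' Scaling `adjusted_ratio` acts on the *signed* value: an 80% factor on
#' a dominant (negative) ratio makes it less negative, i.e. shrinks its
#' magnitude, consistent with reading "80–120% of the original value" as
#' multiplicative. Use `shift` for an absolute-shift perturbation
#' instead.
#'
#' The QALY threshold is not a record field; threshold scenarios are
#' evaluated directly via [welfare_at_thresholds()].
#'
#' @param basket A basket tibble.
#' @param parameter One of `"n_users"`, `"adjusted_ratio"`,
#'   `"delta_effect"`, `"time_horizon"`.
#' @param factor Positive multiplicative factor.
#' @param shift Absolute shift applied after scaling (default 0).
#' @return The perturbed basket.
#' @export
perturb_basket <- function(basket, parameter, factor, shift = 0) {
  if (identical(parameter, "threshold")) {
    rlang::abort(
      "The threshold is perturbed at evaluation time; use welfare_at_thresholds().",
      class = "drugwelfare_parameter_error")
  }
  if (!is.character(parameter) || length(parameter) != 1L ||
      !parameter %in% record_parameters) {
    rlang::abort(
      sprintf("Unknown parameter; expected one of: %s.",
              paste(record_parameters, collapse = ", ")),
      class = "drugwelfare_parameter_error")
  }
  if (!is.finite(factor) || factor <= 0) {
    rlang::abort("`factor` must be > 0.",
                 class = "drugwelfare_validation_error")
  }
  col <- switch(parameter,
                n_users = "n_users",
                adjusted_ratio = "ratio_target_amount",
                delta_effect = "delta_effect",
                time_horizon = "time_horizon_years")
  out <- basket
  out[[col]] <- out[[col]] * factor + shift
  out
}

#' Default univariate perturbation plan
#'
#' The standard one-way plan: harmonized ratio, incremental effect and
#' time horizon each varied to 80% and 120% of their base values; the
#' user counts varied to 50% and 150% (since effect and users enter the
#' formula symmetrically, a ±20% user variation would duplicate the
#' effect scenario); and the threshold evaluated at 50,000 and 150,000
#' in place of the 100,000 base case.
#'
#' @param low_threshold,high_threshold Alternative thresholds.
#' @param ratio_factors,effect_factors,horizon_factors,users_factors
#'   Length-2 `(low, high)` multiplicative factors.
#' @return A named list understood by [run_sensitivity()].
#' @export
sensitivity_plan <- function(low_threshold = 50000, high_threshold = 150000,
                             ratio_factors = c(0.8, 1.2),
                             effect_factors = c(0.8, 1.2),
                             horizon_factors = c(0.8, 1.2),
                             users_factors = c(0.5, 1.5)) {
  list(thresholds = c(low_threshold, high_threshold),
       factors = tibble::tibble(
         parameter = c("adjusted_ratio", "delta_effect", "time_horizon",
                       "n_users"),
         low = c(ratio_factors[1], effect_factors[1], horizon_factors[1],
                 users_factors[1]),
         high = c(ratio_factors[2], effect_factors[2], horizon_factors[2],
                  users_factors[2])))
}

#' Univariate sensitivity analysis with tornado ranking
#'
#' Perturbs one parameter class at a time per `plan`, recomputes the
#' basket total for each scenario, and ranks the parameters by the range
#' their variation induces (rank 1 = widest bar in the tornado diagram;
#' ties broken alphabetically). Bar endpoints are scenario *totals*, not
#' deltas from base, so the global minimum and maximum across scenarios
#' are read off directly.
#'
#' @param basket A basket tibble, fully populated with users.
#' @param base_threshold Base-case threshold.
#' @param plan A [sensitivity_plan()].
#' @return A list of class `sensitivity_result`: `tornado` (tibble
#'   `parameter,low_total,high_total,range,rank` in rank order),
#'   `base_total`, `min_total`, `max_total`, and `scenarios` (every
#'   scenario total, long form).
#' @examples
#' fx <- table2_fixture()
#' basket <- populate_users(fx$basket, welfare = fx$welfare)
#' run_sensitivity(basket)$tornado
#' @export
run_sensitivity <- function(basket, base_threshold = 100000,
                            plan = sensitivity_plan()) {
  check_evaluable(basket)
  base_total <- total_welfare(basket, base_threshold)$total
  thr <- welfare_at_thresholds(basket, plan$thresholds, base_threshold)
  rows <- list(tibble::tibble(
    parameter = "threshold",
    low_total = thr$total[1], high_total = thr$total[2]))
  scen <- list(tibble::tibble(
    parameter = "threshold", side = c("low", "high"),
    setting = plan$thresholds, total = thr$total))
  for (i in seq_len(nrow(plan$factors))) {
    p <- plan$factors$parameter[i]
    eval_at <- function(f) {
      tryCatch(
        total_welfare(perturb_basket(basket, p, f), base_threshold)$total,
        error = function(e) {
          rlang::abort(
            sprintf("Scenario '%s x %g' failed: %s", p, f,
                    conditionMessage(e)),
            class = "drugwelfare_scenario_error")
        })
    }
    lo <- eval_at(plan$factors$low[i])
    hi <- eval_at(plan$factors$high[i])
    rows[[length(rows) + 1L]] <- tibble::tibble(
      parameter = p, low_total = lo, high_total = hi)
    scen[[length(scen) + 1L]] <- tibble::tibble(
      parameter = p, side = c("low", "high"),
      setting = c(plan$factors$low[i], plan$factors$high[i]),
      total = c(lo, hi))
  }
  tornado <- dplyr::bind_rows(rows)
  tornado$range <- abs(tornado$high_total - tornado$low_total)
  # rank 1 = largest range; ties broken alphabetically by parameter
  ord <- order(-tornado$range, tornado$parameter)
  tornado <- tornado[ord, ]
  tornado$rank <- seq_len(nrow(tornado))
  scenarios <- dplyr::bind_rows(scen)
  structure(
    list(tornado = tornado, base_total = base_total,
         min_total = min(scenarios$total), max_total = max(scenarios$total),
         scenarios = scenarios),
    class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf(
    "<sensitivity_result> base %.2f M; scenarios span %.2f M to %.2f M\n",
    x$base_total / 1e6, x$min_total / 1e6, x$max_total / 1e6))
  print(x$tornado)
  invisible(x)
}

#' Write the tornado table to CSV
#'
#' Columns `parameter,low_total,high_total,range,rank`, plus
#' `delta_low`/`delta_high` (totals minus base) for readers who prefer
#' deltas.
#'
#' @param result A `sensitivity_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tornado <- function(result, path) {
  out <- result$tornado
  out$delta_low <- out$low_total - result$base_total
  out$delta_high <- out$high_total - result$base_total
  readr::write_csv(out, path)
  invisible(path)
}

#' Tornado diagram of a sensitivity result
#'
#' Horizontal bars from each parameter's low-scenario total to its
#' high-scenario total, widest on top, with the base-case total marked.
#' Requires ggplot2.
#'
#' @param result A `sensitivity_result`.
#' @return A ggplot object.
#' @export
plot_tornado <- function(result) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    rlang::abort("plot_tornado() requires ggplot2.")
  }
  tor <- result$tornado
  tor$parameter <- factor(tor$parameter, levels = rev(tor$parameter))
  ggplot2::ggplot(tor) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$low_total / 1e6, xend = .data$high_total / 1e6,
                   y = .data$parameter, yend = .data$parameter),
      linewidth = 6, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = result$base_total / 1e6,
                        linetype = "dashed") +
    ggplot2::labs(x = "Total annual welfare impact (million, target currency)",
                  y = NULL) +
    ggplot2::theme_minimal()
}
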