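# Shared fixtures built in code.

ref_fixture <- table2_fixture()

ref_populated <- populate_users(ref_fixture$basket, welfare = ref_fixture$welfare)

# A tiny hand-built basket whose welfare values are trivial to recompute
# by hand: per-user annual net benefit = (threshold - ratio) * delta / T.
toy_basket <- function() {
  tibble::tibble(
    name = c("alpha", "beta", "gamma"),
    brand = c("A", "B", "C"),
    ratio_amount = c(40000, -10000, 120000),
    ratio_currency = c("GBP", "USD", "CHF"),
    ratio_price_year = c(2004L, 2005L, 2010L),
    ratio_outcome_unit = c("QALY", "LY", "QALY"),
    ratio_target_amount = c(50000, -12000, 120000),
    delta_effect = c(0.5, 2, 0.1),
    time_horizon_years = c(10, 4, 2),
    n_users = c(100, 20, 50),
    perspective = "test",
    user_source = "synthetic")
}

random_money <- function() {
  money_per_outcome(
    amount = stats::runif(1, -250000, 250000),
    currency = sample(c("GBP", "AUD", "CAD", "USD", "EUR"), 1),
    price_year = sample(2000:2009, 1),
    outcome_unit = sample(c("QALY", "LY", "MLY"), 1))
}
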