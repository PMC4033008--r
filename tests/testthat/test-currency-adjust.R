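simple_tables <- function() {
  adjustment_tables(
    deflator = data.frame(
      currency = rep(c("GBP", "CHF"), each = 2),
      year = rep(c(2004, 2010), 2),
      value = c(95, 104.5, 96.7, 100)),
    ppp = data.frame(currency = c("GBP", "CHF"), year = 2010,
                     value = c(2, 1)))
}

test_that("deflation scales by the within-currency index ratio", {
  tabs <- simple_tables()
  out <- deflate(money_per_outcome(100, "GBP", 2004, "QALY"), tabs)
  expect_equal(out$amount, 100 * 104.5 / 95)
  expect_equal(out$price_year, 2010L)
  expect_equal(out$currency, "GBP")

  # already at target year: identity
  same <- money_per_outcome(123.45, "GBP", 2010, "QALY")
  expect_equal(deflate(same, tabs), same)

  # dominant ratios stay negative under any positive factor
  dom <- deflate(money_per_outcome(-27047, "GBP", 2004, "/LYG"), tabs)
  expect_lt(dom$amount, 0)
})

test_that("PPP conversion applies the target-year rate and is identity on the target currency", {
  tabs <- simple_tables()
  out <- ppp_convert(money_per_outcome(50000, "GBP", 2010, "QALY"), tabs)
  expect_equal(out$amount, 100000)
  expect_equal(out$currency, "CHF")

  chf <- money_per_outcome(77, "CHF", 2010, "QALY")
  expect_equal(ppp_convert(chf, tabs), chf)

  neg <- ppp_convert(money_per_outcome(-50000, "GBP", 2010, "QALY"), tabs)
  expect_equal(neg$amount, -100000)

  # refuses to convert before deflation
  expect_error(ppp_convert(money_per_outcome(1, "GBP", 2004, "QALY"), tabs),
               class = "drugwelfare_sequence_error")
})

test_that("the two-step harmonization reproduces the pinned bosentan row", {
  tabs <- synthetic_adjustment_fixture()
  out <- adjust_ratio(money_per_outcome(55927, "AUD", 2004, "/LYG"), tabs)
  expect_equal(out$amount, 63562.2, tolerance = 1e-9)
  expect_equal(out$currency, "CHF")
  expect_equal(out$price_year, 2010L)

  # target-currency, target-year input is a fixed point
  chf <- money_per_outcome(46906, "CHF", 2010, "QALY")
  expect_equal(adjust_ratio(chf, tabs), chf)
})

test_that("harmonization is homogeneous in the amount and preserves sign", {
  tabs <- synthetic_adjustment_fixture()
  base <- adjust_ratio(money_per_outcome(1000, "GBP", 2004, "QALY"), tabs)
  for (k in c(-3.5, -1, 0.25, 7)) {
    scaled <- adjust_ratio(money_per_outcome(1000 * k, "GBP", 2004, "QALY"),
                           tabs)
    expect_equal(scaled$amount, k * base$amount, tolerance = 1e-12)
  }
})

test_that("deflate-then-ppp and ppp-then-deflate differ when inflation differs across areas", {
  # same PPP rate, different inflation: applying target-year PPP before
  # deflation would use the wrong price level
  tabs <- simple_tables()
  ratio <- money_per_outcome(100, "GBP", 2004, "QALY")
  pinned <- adjust_ratio(ratio, tabs)$amount          # deflate in GBP, then x2
  swapped <- {
    in_chf <- money_per_outcome(ratio$amount * 2, "CHF", 2004, "QALY")
    deflate(in_chf, tabs)$amount                       # deflate in CHF instead
  }
  expect_false(isTRUE(all.equal(pinned, swapped)))
  # and they coincide when both areas share the deflator path
  expect_equal(pinned / swapped, (104.5 / 95) / (100 / 96.7), tolerance = 1e-12)
})

test_that("harmonization agrees with the literal two-multiplication oracle", {
  tabs <- generate_adjustment_tables(
    c("GBP", "AUD", "CAD", "USD", "EUR", "CHF"), 2000:2010, seed = 99)
  withr::with_seed(2024, {
    for (i in seq_len(1000)) {
      m <- random_money()
      got <- adjust_ratio(m, tabs)$amount
      d_from <- tabs$deflator$value[tabs$deflator$currency == m$currency &
                                      tabs$deflator$year == m$price_year]
      d_to <- tabs$deflator$value[tabs$deflator$currency == m$currency &
                                    tabs$deflator$year == 2010]
      p <- tabs$ppp$value[tabs$ppp$currency == m$currency]
      want <- m$amount * (d_to / d_from) * p
      expect_equal(got, want, tolerance = 1e-12)
    }
  })
})

test_that("implied adjustment factors of the reference basket are finite, positive, and in band", {
  f <- implied_adjustment_factor(ref_fixture$basket)
  expect_length(f, 31)
  expect_true(all(is.finite(f) & f > 0))
  expect_true(all(f >= 0.8 & f <= 2.2))
  names(f) <- ref_fixture$basket$name
  expect_equal(unname(f["Bosentan monohydrate"]), 63562.2 / 55927,
               tolerance = 1e-12)
  expect_equal(unname(f["Raltegravir"]), 46906 / 45687, tolerance = 1e-12)
  expect_equal(unname(f["Raltegravir"]), 1.02668, tolerance = 1e-5)
  # a row equal to its own harmonized value implies factor 1
  b <- ref_fixture$basket[1, ]
  b$ratio_target_amount <- b$ratio_amount
  expect_equal(implied_adjustment_factor(b), 1)
})

test_that("bundled implied-factor calibration artifact matches the basket", {
  cal <- readr::read_csv(
    system.file("extdata", "table2_implied_factors.csv",
                package = "drugwelfare", mustWork = TRUE),
    show_col_types = FALSE)
  expect_equal(cal$implied_factor,
               implied_adjustment_factor(ref_fixture$basket),
               tolerance = 1e-6)
})
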