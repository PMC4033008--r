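test_that("the bundled reference basket parses to 31 complete records", {
  basket <- ref_fixture$basket
  expect_equal(nrow(basket), 31L)
  expect_equal(nrow(attr(basket, "diagnostics")), 0L)
  expect_true(all(basket$time_horizon_years > 0))
  expect_true(all(basket$delta_effect > 0))
  expect_true(all(is.na(basket$n_users)))  # confidential, never 0
})

test_that("a named fixture row carries the printed values", {
  cin <- ref_fixture$basket[ref_fixture$basket$name == "Cinacalcet", ]
  expect_equal(cin$ratio_amount, 61890)
  expect_equal(cin$ratio_currency, "GBP")
  expect_equal(cin$ratio_price_year, 2004L)
  expect_equal(cin$ratio_target_amount, 104433.05)
  expect_equal(cin$delta_effect, 0.34)
  expect_equal(cin$time_horizon_years, 24.1)
})

test_that("an empty file with only a header yields an empty basket", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(paste(drugwelfare:::basket_columns, collapse = ","), path)
  basket <- read_basket(path)
  expect_equal(nrow(basket), 0L)
  expect_equal(nrow(attr(basket, "diagnostics")), 0L)
})

test_that("schema mapping resolves foreign headers and missing columns are named", {
  path <- withr::local_tempfile(fileext = ".csv")
  b <- toy_basket()
  names(b)[names(b) == "name"] <- "drug"
  readr::write_csv(b, path)
  got <- read_basket(path, schema_config = c(name = "drug"))
  expect_equal(got$name, c("alpha", "beta", "gamma"))
  expect_error(read_basket(path), class = "drugwelfare_schema_error")
  expect_error(read_basket(path, schema_config = c(name = "nonexistent")),
               class = "drugwelfare_schema_error")
})

test_that("invalid rows are rejected with row-indexed diagnostics, none silently", {
  b <- toy_basket()
  b$time_horizon_years[2] <- -1          # invariant violation
  b$ratio_currency[3] <- "FRANCS"        # unknown currency code
  b <- dplyr::bind_rows(b, b[1, ])
  b$delta_effect[4] <- 0                 # zero incremental effect
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(b, path)
  expect_warning(got <- read_basket(path), "rejected")
  diag <- attr(got, "diagnostics")
  expect_equal(nrow(got) + nrow(diag), nrow(b))   # no silent drops
  expect_equal(diag$row, c(2L, 3L, 4L))
  expect_match(diag$message[diag$row == 2L], "horizon")
})

test_that("unparseable numerics are row errors naming row and field", {
  b <- toy_basket()
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(b, path)
  txt <- readLines(path)
  txt[2] <- sub("40000", "not-a-number", txt[2])
  writeLines(txt, path)
  expect_warning(got <- read_basket(path), "rejected")
  diag <- attr(got, "diagnostics")
  expect_equal(diag$row, 1L)
  expect_equal(diag$field, "ratio_amount")
})

test_that("basket round trip is the identity on valid records", {
  b <- ref_fixture$basket
  path <- withr::local_tempfile(fileext = ".csv")
  write_basket(b, path)
  got <- read_basket(path)
  expect_equal(nrow(got), nrow(b))
  expect_equal(got$name, b$name)                      # order preserved
  expect_equal(got$ratio_amount, b$ratio_amount, tolerance = 1e-9)
  expect_equal(got$ratio_target_amount, b$ratio_target_amount,
               tolerance = 1e-9)
  expect_equal(got$delta_effect, b$delta_effect)
  expect_equal(got$time_horizon_years, b$time_horizon_years)
})

test_that("normalization is idempotent: units and currencies reach a fixed point", {
  expect_equal(drugwelfare:::normalize_outcome_unit(
    c("/LYG", "LYG", "ly", "QALY", "/MLY")),
    c("LY", "LY", "LY", "QALY", "MLY"))
  once <- drugwelfare:::normalize_outcome_unit("/LYG")
  expect_identical(drugwelfare:::normalize_outcome_unit(once), once)
  expect_equal(drugwelfare:::normalize_currency("chf"), "CHF")
  expect_identical(drugwelfare:::normalize_currency("CHF"), "CHF")
})

test_that("adjustment tables read, look up, and round-trip", {
  tabs <- synthetic_adjustment_fixture()
  expect_s3_class(tabs, "adjustment_tables")
  expect_gt(drugwelfare:::deflator_at(tabs, "CHF", 2006), 0)
  path <- withr::local_tempfile(fileext = ".csv")
  write_adjustment_tables(tabs, path)
  back <- read_adjustment_tables(path)
  expect_equal(back$deflator, tabs$deflator)
  expect_equal(back$ppp, tabs$ppp)
})

test_that("missing table entries are completeness errors naming the cell", {
  tabs <- adjustment_tables(
    deflator = data.frame(currency = "CHF", year = c(2006, 2010),
                          value = c(96.7, 100)),
    ppp = data.frame(currency = "CHF", year = 2010, value = 1))
  expect_equal(drugwelfare:::deflator_at(tabs, "CHF", 2006), 96.7)
  err <- expect_error(
    deflate(money_per_outcome(100, "AUD", 2004, "QALY"), tabs),
    class = "drugwelfare_completeness_error")
  expect_match(conditionMessage(err), "AUD, 2004")
  expect_error(
    adjustment_tables(
      deflator = data.frame(currency = "CHF", year = 2010, value = -1),
      ppp = data.frame(currency = "CHF", year = 2010, value = 1)),
    class = "drugwelfare_validation_error")
})

test_that("welfare reports serialize with a TOTAL row and survive a round trip", {
  tw <- total_welfare(toy_basket())
  path <- withr::local_tempfile(fileext = ".csv")
  write_results(tw, path)
  lines <- readLines(path)
  expect_equal(length(lines), 3 + 1 + 1)  # header + drugs + TOTAL
  back <- read_results(path)
  expect_equal(nrow(back$per_drug), 3)
  expect_equal(back$total, tw$total, tolerance = 0.01 / max(1, abs(tw$total)))

  # zero-welfare result totals exactly 0.00
  z <- toy_basket()[1, ]
  z$ratio_target_amount <- 100000
  write_results(total_welfare(z), path)
  expect_equal(read_results(path)$total, 0)

  # SLOPE row carries the aggregate annual QALYs
  write_results(tw, path, include_slope = TRUE)
  raw <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(raw$annual_effect[raw$name == "SLOPE"], tw$slope)
})
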