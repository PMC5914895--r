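test_that("cost items validate vocabularies and allocation bounds", {
  amt <- money(100, "USD", 2015)
  expect_error(cost_item("x", "setup", "staff", "financial", amt), "phase")
  expect_error(cost_item("x", "start_up", "misc", "financial", amt), "category")
  expect_error(cost_item("x", "start_up", "staff", "guessed", amt), "cost_basis")
  expect_error(cost_item("x", "start_up", "staff", "financial", amt, 1.2),
               "allocation_fraction")

  it <- cost_item("x", "start_up", "staff", "financial", amt, 0.25)
  expect_equal(allocate(it), 25)
  expect_equal(allocate(cost_item("y", "start_up", "staff", "financial", amt, 1)), 100)
  expect_equal(allocate(cost_item("z", "start_up", "staff", "financial", amt, 0)), 0)
})

test_that("resolve_ledger pins the convert-then-inflate order", {
  # 370000 UGX spent in 2013 at 3700 UGX/USD, CPI 100 -> 110, allocated 50%:
  # (370000 / 3700) * 110/100 * 0.5 = 55. Inflating in UGX first with the
  # same (US) CPI then converting at the 2013 rate would give the same
  # number only because the rate is year-of-expenditure; converting at a
  # hypothetical 2015 rate of 3000 would give 67.83 instead.
  ledger <- cost_ledger(
    list(cost_item("a", "implementation", "recurrent", "financial",
                   money(370000, "UGX", 2013), 0.5)),
    list(), 2015, "USD", 1.5
  )
  rt <- list(UGX = c("2013" = 3700, "2015" = 3000))
  cpi <- c("2013" = 100, "2015" = 110)
  resolved <- resolve_ledger(ledger, rt, cpi)
  expect_equal(resolved$value, 55)
  wrong_order <- 370000 * 1.10 / 3000 * 0.5
  expect_false(isTRUE(all.equal(resolved$value, wrong_order)))
})

test_that("capital assets enter aggregation as EAC x horizon x allocation", {
  ledger <- cost_ledger(
    list(cost_item("fixed", "implementation", "recurrent", "financial",
                   money(100, "USD", 2015))),
    list(capital_asset("laptop", money(1000, "USD", 2015), 5, 0, 0,
                       phase = "implementation", category = "capital",
                       allocation_fraction = 0.5)),
    2015, "USD", 1.5
  )
  by_cat <- aggregate_costs(ledger, list(), c("2015" = 100), "category")
  # straight-line 1000/5 = 200/yr, x 1.5 yr x 0.5 allocation = 150
  expect_equal(by_cat$total[by_cat$group == "capital"], 150)
  expect_equal(attr(by_cat, "grand_total"), 250)
})

test_that("aggregation reproduces published-style totals and integer percents", {
  sim <- simulate_ledger(table1_profile(), seed = 42)
  by_phase <- aggregate_costs(sim$ledger, sim$exchange_rates, sim$cpi, "phase")
  by_cat <- aggregate_costs(sim$ledger, sim$exchange_rates, sim$cpi, "category")

  expect_equal(attr(by_phase, "grand_total"), 397233, tolerance = 1e-9)
  expect_equal(by_phase$total[by_phase$group == "start_up"], 117949, tolerance = 1e-9)
  expect_equal(by_phase$total[by_phase$group == "implementation"], 279284, tolerance = 1e-9)
  expect_identical(by_phase$percent, c(30, 70))

  expect_equal(by_cat$total, c(156441, 69164, 171628), tolerance = 1e-9)
  expect_identical(by_cat$percent, c(39, 17, 43))

  # single item dominates its scope
  single <- cost_ledger(
    list(cost_item("only", "start_up", "staff", "financial", money(77, "USD", 2015))),
    list(), 2015, "USD", 1
  )
  one <- aggregate_costs(single, list(), c("2015" = 100), "phase")
  expect_identical(one$percent, 100)
})

test_that("monitoring and evaluation lines are excluded unless asked for", {
  ledger <- toy_ledger()
  ledger$items <- c(ledger$items, list(
    cost_item("process monitor", "monitoring_evaluation", "staff", "financial",
              money(999, "USD", 2015))
  ))
  without <- aggregate_costs(ledger, list(), c("2015" = 100), "phase")
  with_me <- aggregate_costs(ledger, list(), c("2015" = 100), "phase",
                             include_me = TRUE)
  expect_equal(attr(with_me, "grand_total") - attr(without, "grand_total"), 999)
  expect_false("monitoring_evaluation" %in% without$group)
})

test_that("empty ledgers cannot be aggregated", {
  empty <- cost_ledger(list(), list(), 2015, "USD", 1)
  expect_error(aggregate_costs(empty, list(), c("2015" = 100), "phase"), "empty")
})

test_that("ledger CSV round-trips and degenerate rows fail with row numbers", {
  cfg <- list(base_year = 2015, base_currency = "USD", discount_rate = 0.0926,
              horizon_years = 1.5)
  ledger <- cost_ledger(
    list(cost_item("a", "start_up", "staff", "financial", money(100, "USD", 2014), 0.7)),
    list(capital_asset("dev", money(446940, "USD", 2015), 7, 1, 0.0926)),
    2015, "USD", 1.5
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_ledger_csv(ledger, path)
  back <- read_cost_ledger(path, cfg)
  expect_length(back$items, 1)
  expect_length(back$capital_assets, 1)
  expect_equal(back$items[[1]]$allocation_fraction, 0.7)
  expect_equal(back$capital_assets[[1]]$principal$value, 446940)
  expect_equal(back$capital_assets[[1]]$discount_rate, 0.0926)

  df <- utils::read.csv(path)
  df$value[1] <- 0
  bad <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, bad, row.names = FALSE)
  expect_error(read_cost_ledger(bad, cfg), "row 1")

  df2 <- utils::read.csv(path)
  df2$category[2] <- NA
  bad2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df2, bad2, row.names = FALSE)
  expect_error(read_cost_ledger(bad2, cfg), "row 2")
})

test_that("unit costs divide and report half-up", {
  u <- unit_cost(157343, 21, "annual per school")
  expect_equal(as.numeric(u), 157343 / 21)
  expect_equal(attr(u, "reported"), 7493)
  expect_equal(as.numeric(unit_cost(42.7, 1)), 42.7)
  expect_error(unit_cost(100, 0), "positive")
})

test_that("half-up rounding follows the commercial convention", {
  expect_equal(round_half_up(7492.5), 7493)
  expect_equal(round_half_up(c(0.5, 1.5, 2.5)), c(1, 2, 3))
  expect_equal(round_half_up(-2.5), -3)
  expect_equal(round_half_up(0.125, 2), 0.13)
})
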