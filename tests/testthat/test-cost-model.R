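test_that("annuity factor matches the summed discount series and its limits", {
  expect_equal(annuity_factor(0, 5), 5)
  expect_equal(annuity_factor(0.03, 10), 8.530203, tolerance = 1e-6)
  expect_equal(annuity_factor(0.03, 3), 2.828611, tolerance = 1e-6)
  for (rate in c(0.01, 0.03, 0.05, 0.12)) {
    for (n in c(1, 3, 7, 10, 25)) {
      expect_equal(annuity_factor(rate, n), af_oracle(rate, n),
                   tolerance = 1e-12)
    }
  }
  # continuity at rate -> 0
  expect_equal(annuity_factor(1e-12, 8), 8, tolerance = 1e-9)
})

test_that("annuity factor is monotone in life and in rate", {
  for (rate in c(0.01, 0.03, 0.08)) {
    af <- vapply(1:20, function(n) annuity_factor(rate, n), numeric(1))
    expect_true(all(diff(af) > 0))
  }
  rates <- c(0.005, 0.01, 0.03, 0.05, 0.1)
  af <- vapply(rates, function(r) annuity_factor(r, 10), numeric(1))
  expect_true(all(diff(af) < 0))
})

test_that("annuity factor rejects bad arguments by name", {
  expect_error(annuity_factor(-0.01, 5), "rate")
  expect_error(annuity_factor(0.03, 0), "n_years")
  expect_error(annuity_factor(0.03, 2.5), "n_years")
})

test_that("annualize_item divides capital by the discounted series oracle", {
  pol <- annualization_policy()
  it <- cost_line_item("laptops", "it_equipment", "start_up", "intervention",
                       1000, is_capital = TRUE, useful_life_years = 5)
  expect_equal(annualize_item(it, pol), 1000 / af_oracle(0.03, 5),
               tolerance = 1e-9)
  expect_equal(round(annualize_item(it, pol), 2), 218.35)

  # recurrent items pass through unchanged
  rec <- cost_line_item("incentives", "asha_incentive", "implementation",
                        "intervention", 35166)
  expect_identical(annualize_item(rec, pol), 35166)

  # straight line at zero discount
  pol0 <- annualization_policy(discount_rate = 0)
  it10 <- cost_line_item("app", "software_development", "start_up",
                         "intervention", 1000, is_capital = TRUE,
                         useful_life_years = 10)
  expect_equal(annualize_item(it10, pol0), 100)
})

test_that("useful life resolves from the policy's category defaults", {
  pol <- annualization_policy()
  led <- capital_ledger()
  ann <- annualize_ledger(led, pol)
  expect_equal(ann$annualized[1], 50000 / af_oracle(0.03, 10), tolerance = 1e-9)
  expect_equal(ann$annualized[2], 7000 / af_oracle(0.03, 7), tolerance = 1e-9)
  expect_equal(ann$annualized[4], 9000 / af_oracle(0.03, 3), tolerance = 1e-9)
  expect_equal(ann$annualized[5:6], c(24000, 35000))

  # capital item with no resolvable life is rejected
  bad <- cost_line_item("generator", "other", "start_up", "intervention",
                        5000, is_capital = TRUE)
  expect_error(annualize_item(bad, pol), "useful life")
})

test_that("ledger validation reports the offending row", {
  led <- capital_ledger()
  led$amount[3] <- -5
  expect_error(validate_cost_ledger(led), "row 3")
  led2 <- capital_ledger()
  led2$phase[2] <- "setup"
  expect_error(validate_cost_ledger(led2), "phase 'setup'")
})

test_that("cost summaries aggregate by category and phase consistently", {
  pol <- annualization_policy()
  s <- summarize_costs(capital_ledger(), "intervention", pol)
  expect_equal(s$grand_total, sum(s$by_category), tolerance = 1e-9)
  expect_equal(s$grand_total, sum(s$phase_totals), tolerance = 1e-9)
  expect_equal(sum(s$percent_by_item), 100, tolerance = 1e-9)

  # permutation invariance
  set.seed(1)
  perm <- capital_ledger()[sample(6), ]
  expect_equal(summarize_costs(perm, "intervention", pol), s)

  # additivity over disjoint ledgers
  a <- capital_ledger()[1:3, ]
  b <- capital_ledger()[4:6, ]
  expect_equal(summarize_costs(a, "intervention", pol)$grand_total +
                 summarize_costs(b, "intervention", pol)$grand_total,
               s$grand_total, tolerance = 1e-9)
})

test_that("degenerate ledgers summarize without error", {
  empty <- capital_ledger()[0, ]
  s <- summarize_costs(empty, "intervention")
  expect_equal(s$grand_total, 0)
  expect_true(all(s$by_category == 0))
  expect_true(all(s$percent_by_item == 0))

  one <- cost_line_item("only", "personnel", "implementation",
                        "intervention", 100)
  s1 <- summarize_costs(one, "intervention")
  expect_equal(s1$grand_total, 100)
  expect_equal(unname(s1$percent_by_item["personnel"]), 100)
})

test_that("summarize_costs rejects rows from the wrong arm", {
  led <- capital_ledger()
  expect_error(summarize_costs(led, "control"), "arm 'intervention'")
})

test_that("incremental cost has the right sign convention and warns on price-year mismatch", {
  pol <- annualization_policy()
  si <- summarize_costs(capital_ledger("intervention"), "intervention", pol)
  sc <- summarize_costs(capital_ledger("control"), "control", pol)
  expect_equal(as.numeric(incremental_cost(si, sc)), 0, tolerance = 1e-9)

  cheap <- summarize_costs(
    cost_line_item("x", "personnel", "implementation", "intervention", 100),
    "intervention", pol)
  dear <- summarize_costs(
    cost_line_item("y", "personnel", "implementation", "control", 250),
    "control", pol)
  expect_equal(as.numeric(incremental_cost(cheap, dear)), -150)

  pol2 <- annualization_policy(price_year = "2020")
  sc2 <- summarize_costs(capital_ledger("control"), "control", pol2)
  expect_warning(d <- incremental_cost(si, sc2), "price-year")
  expect_true(attr(d, "price_year_mismatch"))
})
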