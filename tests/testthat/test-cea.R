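ref_effect <- function() effect_estimate(10.74983, 3014, 2740)

test_that("life-years and cost normalizations follow their definitions", {
  expect_equal(life_years_saved_per_1000(0, 68.35), 0)
  expect_equal(life_years_saved_per_1000(1, 68.35), 68.35)
  expect_equal(round(life_years_saved_per_1000(10.75, 68.35), 1), 734.8)
  expect_equal(round(life_years_saved_per_1000(10.75, 68.35)), 735)

  expect_equal(round(cost_per_1000_live_births(163841, 3014)), 54360)
  expect_equal(round(cost_per_1000_live_births(163841, 4171)), 39281)
  expect_equal(cost_per_1000_live_births(0, 3014), 0)
  expect_error(cost_per_1000_live_births(100, 0), "live_births_intervention")
})

test_that("the ICER panel chains unrounded and satisfies its identities", {
  params <- cea_parameters(incremental_cost_annual = 163841)
  res <- icer_panel(params, ref_effect())
  expect_equal(res$cost_per_1000_live_births, 1000 * res$cost_per_live_birth)
  expect_equal(res$cost_per_lys * 68.35, res$cost_per_death_averted,
               tolerance = 1e-12)
  expect_equal(res$cost_per_death_averted,
               res$cost_per_1000_live_births / res$deaths_averted_per_1000,
               tolerance = 1e-12)
  expect_identical(res$verdict, "cost_effective")
})

test_that("panel ratios are scale-invariant in cost and denominator", {
  for (k in c(0.25, 2, 13)) {
    a <- icer_panel(cea_parameters(163841), effect_estimate(10.75, 3014, 2740))
    b <- icer_panel(cea_parameters(163841 * k),
                    effect_estimate(10.75, 3014 * k, 2740 * k))
    expect_equal(a$cost_per_1000_live_births, b$cost_per_1000_live_births,
                 tolerance = 1e-9)
    expect_equal(a$cost_per_death_averted, b$cost_per_death_averted,
                 tolerance = 1e-9)
    expect_equal(a$cost_per_lys, b$cost_per_lys, tolerance = 1e-9)
  }
})

test_that("zero effect flags ratios undefined; zero cost is dominant", {
  null_eff <- effect_estimate(0, 3014, 2740)
  res <- icer_panel(cea_parameters(163841), null_eff)
  expect_true(res$ratios_undefined)
  expect_true(is.na(res$cost_per_death_averted))
  expect_identical(res$verdict, "not_cost_effective")

  free <- icer_panel(cea_parameters(0), ref_effect())
  expect_equal(free$cost_per_death_averted, 0)
  expect_equal(free$cost_per_lys, 0)
  expect_identical(free$verdict, "dominant")
})

test_that("the GDP-threshold verdict is strict and monotone", {
  expect_identical(classify(74, 1709, 1, 1), "cost_effective")
  expect_identical(classify(1709, 1709, 1, 1), "not_cost_effective")
  expect_identical(classify(NA_real_, 1709, -1, 1), "dominant")
  expect_identical(classify(NA_real_, 1709, 1, -1), "dominated")
  # raising the threshold never flips cost_effective -> not
  for (cpl in c(10, 500, 1700, 1710, 5000)) {
    verdicts <- vapply(c(1000, 1709, 3000, 10000), function(g)
      classify(cpl, g, 1, 1), character(1))
    ce <- verdicts == "cost_effective"
    expect_true(all(diff(ce) >= 0))
  }
})

test_that("optional discounting of life-years preserves the panel identity", {
  params <- cea_parameters(163841, lys_discount_rate = 0.03)
  res <- icer_panel(params, ref_effect())
  lyd <- af_oracle(0.03, 68)
  expect_equal(res$lys_per_1000, 10.74983 * lyd, tolerance = 1e-9)
  expect_equal(res$cost_per_lys * lyd, res$cost_per_death_averted,
               tolerance = 1e-9)
  expect_gt(res$cost_per_lys, icer_panel(cea_parameters(163841),
                                         ref_effect())$cost_per_lys)
})

test_that("decision tree reproduces the direct incremental arithmetic", {
  tree <- two_arm_decision_tree(
    p_death_control = 184 / 2740, p_death_intervention = 170 / 3014,
    cost_per_live_birth_control = 0,
    cost_per_live_birth_intervention = 163841 / 3014,
    life_expectancy = 68.35
  )
  out <- evaluate_decision_tree(tree, births_per_arm = 1000)
  expect_equal(out$deaths_averted, 10.74983, tolerance = 1e-5)
  expect_equal(round(out$cost_per_lys), 74)

  same <- two_arm_decision_tree(0.05, 0.05, 10, 12)
  null <- evaluate_decision_tree(same, 500)
  expect_equal(null$deaths_averted, 0)
  expect_true(is.na(null$cost_per_death_averted))
})

test_that("decision tree and ICER panel agree on randomized draws", {
  set.seed(2024)
  for (i in 1:30) {
    p_c <- runif(1, 0.02, 0.12)
    p_i <- runif(1, 0.01, 0.11)
    if (p_c == p_i) next
    births <- sample(500:6000, 1)
    premium <- runif(1, 5, 120)
    le <- runif(1, 40, 80)
    tree <- two_arm_decision_tree(p_c, p_i, runif(1, 0, 50),
                                  runif(1, 0, 50) , le)
    tree$cost_per_live_birth_intervention <-
      tree$cost_per_live_birth_control + premium
    tree_out <- evaluate_decision_tree(tree, births)
    panel <- icer_panel(
      cea_parameters(premium * births, life_expectancy = le),
      effect_estimate((p_c - p_i) * 1000, births, births)
    )
    expect_equal(tree_out$cost_per_death_averted, panel$cost_per_death_averted,
                 tolerance = 1e-6)
    expect_equal(tree_out$cost_per_lys, panel$cost_per_lys, tolerance = 1e-6)
  }
})

test_that("cost-effectiveness plane quadrants follow the sign pattern", {
  expect_identical(ce_plane_point(163841, 734.8 * 3.014)$quadrant, "NE")
  expect_identical(ce_plane_point(-10, 5)$quadrant, "SE")
  expect_identical(ce_plane_point(10, -5)$quadrant, "NW")
  expect_identical(ce_plane_point(-10, -5)$quadrant, "SW")
  expect_true(is.na(ce_plane_point(0, 0)$quadrant))
  expect_true(is.na(ce_plane_point(0, 5)$quadrant))
})
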