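test_that("record validation normalizes tokens and rejects contradictions", {
  r <- birth_record("a1", arm = "Intervention", outcome = "Live_Birth")
  out <- validate_birth_records(r)
  expect_identical(out$arm, "intervention")
  expect_identical(out$outcome, "live_birth")

  expect_error(validate_birth_records(birth_record("a1", arm = "placebo")),
               "arm token.*placebo")
  expect_error(
    validate_birth_records(
      birth_record("a1", outcome = "stillbirth", window = "neonatal")),
    "stillbirth cannot carry a death window")
  two <- dplyr::bind_rows(birth_record("dup"), birth_record("dup"))
  expect_error(validate_birth_records(two), "duplicate record_id")
})

test_that("cohorts count nested death windows and apply the PP restriction", {
  rec <- dplyr::bind_rows(
    birth_record("r1", window = "early_neonatal"),
    birth_record("r2", window = "neonatal"),
    birth_record("r3", window = "post_neonatal"),
    birth_record("r4"),
    birth_record("r5", native = FALSE, window = "early_neonatal"),
    birth_record("r6", outcome = "stillbirth"),
    birth_record("r7", arm = "control")
  )
  itt <- build_cohort(rec, "ITT")
  int <- itt[itt$arm == "intervention", ]
  expect_equal(int$live_births, 5)
  expect_equal(int$early_neonatal_deaths, 2)
  expect_equal(int$neonatal_deaths, 3)
  expect_equal(int$infant_deaths, 4)
  expect_equal(int$stillbirths, 1)

  pp <- build_cohort(rec, "PP")
  ppi <- pp[pp$arm == "intervention", ]
  expect_equal(ppi$live_births, 4)
  expect_equal(ppi$early_neonatal_deaths, 1)

  expect_error(build_cohort(rec, "modified-ITT"), "analysis_set")
})

test_that("zero records produce an all-zero cohort, not an error", {
  z <- build_cohort(birth_record("x")[0, ], "ITT")
  expect_equal(nrow(z), 2)
  expect_true(all(z$live_births == 0) && all(z$infant_deaths == 0))
})

test_that("build_cohort agrees with a brute-force tally on random inputs", {
  for (seed in 1:6) {
    rec <- random_records(80, seed)
    for (set in c("ITT", "PP")) {
      counts <- build_cohort(rec, set)
      for (arm in c("intervention", "control")) {
        got <- counts[counts$arm == arm, ]
        want <- tally_oracle(rec, set, arm)
        expect_equal(got$live_births, unname(want["live_births"]))
        expect_equal(got$early_neonatal_deaths,
                     unname(want["early_neonatal_deaths"]))
        expect_equal(got$neonatal_deaths, unname(want["neonatal_deaths"]))
        expect_equal(got$infant_deaths, unname(want["infant_deaths"]))
        expect_equal(got$stillbirths, unname(want["stillbirths"]))
      }
    }
  }
})

test_that("count nesting and PP-within-ITT hold on generated data", {
  for (seed in 1:5) {
    rec <- random_records(120, seed + 100)
    itt <- build_cohort(rec, "ITT")
    pp <- build_cohort(rec, "PP")
    for (arm in c("intervention", "control")) {
      a <- itt[itt$arm == arm, ]
      expect_true(a$early_neonatal_deaths <= a$neonatal_deaths)
      expect_true(a$neonatal_deaths <= a$infant_deaths)
      expect_true(a$infant_deaths <= a$live_births)
      p <- pp[pp$arm == arm, ]
      for (col in c("live_births", "early_neonatal_deaths", "neonatal_deaths",
                    "infant_deaths", "stillbirths")) {
        expect_true(p[[col]] <= a[[col]])
      }
    }
  }
})

test_that("rates per 1000 are exact, scale-invariant and guarded", {
  expect_equal(round_rate(rate_per_1000(170, 3014)), 56.4)
  expect_equal(round_rate(rate_per_1000(184, 2740)), 67.2)
  expect_equal(rate_per_1000(0, 500), 0)
  expect_equal(rate_per_1000(17, 301), rate_per_1000(17 * 9, 301 * 9))
  expect_error(rate_per_1000(1, 0), "live_births")
  expect_error(rate_per_1000(10, 5), "exceed")
})

test_that("deaths averted and relative reduction follow their definitions", {
  expect_equal(deaths_averted_per_1000(67.15, 56.40), 10.75)
  expect_equal(deaths_averted_per_1000(50, 50), 0)
  expect_equal(deaths_averted_per_1000(40, 55), -15)  # harm is negative
  expect_equal(relative_reduction(50, 25), 50)
  expect_equal(relative_reduction(42, 42), 0)
  expect_equal(round(relative_reduction(67.15, 56.40)), 16)
  expect_error(relative_reduction(0, 10), "control_rate")
})

test_that("outcome_table reproduces the reference surveillance in every cell", {
  tab <- outcome_table(reference_surveillance())
  expect_equal(tab$ITT_control[tab$variable == "live_births"], 4059)
  expect_equal(tab$ITT_intervention[tab$variable == "live_births"], 4171)
  expect_equal(tab$PP_control[tab$variable == "live_births"], 2740)
  expect_equal(tab$PP_intervention[tab$variable == "live_births"], 3014)
  expect_equal(tab$ITT_control[tab$variable == "infant_deaths"], 236)
  expect_equal(tab$ITT_intervention[tab$variable == "infant_deaths"], 233)
  expect_equal(tab$PP_control[tab$variable == "infant_deaths"], 184)
  expect_equal(tab$PP_intervention[tab$variable == "infant_deaths"], 170)
  expect_equal(tab$ITT_control[tab$variable == "early_neonatal_deaths"], 106)
  expect_equal(tab$ITT_intervention[tab$variable == "early_neonatal_deaths"], 113)
  expect_equal(tab$PP_control[tab$variable == "early_neonatal_deaths"], 81)
  expect_equal(tab$PP_intervention[tab$variable == "early_neonatal_deaths"], 83)
  expect_equal(tab$ITT_control[tab$variable == "neonatal_deaths"], 138)
  expect_equal(tab$ITT_intervention[tab$variable == "neonatal_deaths"], 142)
  expect_equal(tab$PP_control[tab$variable == "neonatal_deaths"], 102)
  expect_equal(tab$PP_intervention[tab$variable == "neonatal_deaths"], 104)
  expect_equal(tab$ITT_control[tab$variable == "stillbirths"], 107)
  expect_equal(tab$ITT_intervention[tab$variable == "stillbirths"], 90)
  expect_equal(tab$PP_control[tab$variable == "stillbirths"], 79)
  expect_equal(tab$PP_intervention[tab$variable == "stillbirths"], 72)

  hosp <- tab[tab$variable == "hospital_deliveries_pct", ]
  expect_equal(round_rate(hosp$ITT_control), 83.5)
  expect_equal(round_rate(hosp$ITT_intervention), 80.3)
  expect_equal(round_rate(hosp$PP_control), 80.8)
  expect_equal(round_rate(hosp$PP_intervention), 77.1)
})

test_that("outcome_table handles the degenerate cases", {
  empty <- outcome_table(birth_record("x")[0, ])
  expect_true(all(empty$ITT_intervention == 0))

  one <- outcome_table(birth_record("solo", window = "early_neonatal"))
  expect_equal(one$ITT_intervention[one$variable == "early_neonatal_deaths"], 1)
  expect_equal(one$ITT_intervention[one$variable == "neonatal_deaths"], 1)
  expect_equal(one$ITT_intervention[one$variable == "infant_deaths"], 1)
})
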