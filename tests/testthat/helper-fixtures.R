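# Independent oracle: annuity factor as an explicitly summed discount series.
af_oracle <- function(rate, n) sum((1 + rate)^-(seq_len(n)))

# Build a birth record row quickly in tests.
birth_record <- function(id, arm = "intervention", native = TRUE,
                         outcome = "live_birth", window = "none",
                         cluster = "phc_01") {
  tibble::tibble(
    record_id = id, cluster_id = cluster, arm = arm,
    mother_native = native, outcome = outcome, death_window = window
  )
}

# Random small record set used by property-style tests.
random_records <- function(n, seed) {
  set.seed(seed)
  windows <- c("none", "early_neonatal", "neonatal", "post_neonatal")
  out <- tibble::tibble(
    record_id = sprintf("r%03d", seq_len(n)),
    cluster_id = sample(sprintf("phc_%02d", 1:4), n, replace = TRUE),
    arm = sample(c("intervention", "control"), n, replace = TRUE),
    mother_native = sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(.7, .3)),
    outcome = sample(c("live_birth", "stillbirth"), n, replace = TRUE,
                     prob = c(.95, .05)),
    death_window = "none"
  )
  live <- out$outcome == "live_birth"
  out$death_window[live] <- sample(windows, sum(live), replace = TRUE,
                                   prob = c(.85, .05, .05, .05))
  out
}

# Brute-force record-by-record tally, independent of build_cohort().
tally_oracle <- function(records, analysis_set, arm) {
  live <- early <- neo <- infant <- still <- 0L
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    if (r$arm != arm) next
    if (analysis_set == "PP" && !r$mother_native) next
    if (r$outcome == "stillbirth") {
      still <- still + 1L
      next
    }
    live <- live + 1L
    if (r$death_window == "early_neonatal") {
      early <- early + 1L; neo <- neo + 1L; infant <- infant + 1L
    } else if (r$death_window == "neonatal") {
      neo <- neo + 1L; infant <- infant + 1L
    } else if (r$death_window == "post_neonatal") {
      infant <- infant + 1L
    }
  }
  c(live_births = live, early_neonatal_deaths = early,
    neonatal_deaths = neo, infant_deaths = infant, stillbirths = still)
}

# A small mixed ledger exercising the annualization path.
capital_ledger <- function(arm = "intervention") {
  tibble::tibble(
    label = c("app build", "motorbikes", "laptops", "orientation",
              "salaries", "incentives"),
    category = c("software_development", "vehicle_two_wheeler",
                 "it_equipment", "training_orientation",
                 "personnel", "asha_incentive"),
    phase = c(rep("start_up", 4), rep("implementation", 2)),
    arm = arm,
    amount = c(50000, 7000, 2500, 9000, 24000, 35000),
    is_capital = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    useful_life_years = c(NA, NA, 5, NA, NA, NA)
  )
}
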