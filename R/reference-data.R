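#' Reference cost ledger (trial accounting, annualized values)
#'
#' The program's published annual cost table, encoded as a ledger whose
#' amounts are the already-annualized category values, flagged
#' non-capital so they pass through [summarize_costs()] unchanged.
#' (Raw capital outlays were not published; the annualization path is
#' exercised by synthetic capital items instead.) The intervention arm
#' carries start-up items (software build, vehicles, handsets, IT
#' equipment, orientation training) and recurrent implementation items
#' (personnel, refresher training, software maintenance, travel, ASHA
#' incentives, IT and office expenses). The control arm carries only the
#' one-time training cost shared with the intervention arm. The published
#' per-item values sum to one dollar less than the published
#' implementation subtotal (a rounding residual of the source accounts),
#' carried here as an explicit `other` line so that the arm totals --
#' 172,052 intervention, 17,789 control -- are reproduced exactly.
#'
#' @param arm `"both"` (default), `"intervention"` or `"control"`.
#' @return a validated cost ledger tibble.
#' @export
reference_cost_ledger <- function(arm = c("both", "intervention", "control")) {
  arm <- match.arg(arm)
  led <- tibble(
    label = c(
      "software development (annualized)", "vehicles (annualized)",
      "mobile handsets (annualized)", "IT equipment (annualized)",
      "orientation training (annualized)",
      "personnel", "refresher training", "software maintenance and upgrades",
      "travel", "ASHA incentives", "IT expenses", "office expenses",
      "rounding residual of published subtotals",
      "orientation training (annualized)"
    ),
    category = c(
      "software_development", "vehicle_two_wheeler", "mobile_handset",
      "it_equipment", "training_orientation",
      "personnel", "training_refresher", "software_maintenance",
      "travel", "asha_incentive", "it_expense", "office_expense", "other",
      "training_orientation"
    ),
    phase = c(rep("start_up", 5), rep("implementation", 8), "start_up"),
    arm = c(rep("intervention", 13), "control"),
    amount = c(7951, 1135, 11873, 397, 24291,
               24919, 256, 49599, 2123, 35166, 12935, 1406, 1,
               17789),
    is_capital = FALSE,
    useful_life_years = NA_real_
  )
  if (arm != "both") {
    led <- led[led$arm == arm, , drop = FALSE]
  }
  validate_cost_ledger(led)
}

# Deterministic record-level expansion of one (arm, native) stratum.
expand_stratum <- function(arm, native, live, early, neonatal, infant,
                           stillbirths, hospital, n_clusters = 11) {
  late_neonatal <- neonatal - early
  post_neonatal <- infant - neonatal
  survivors <- live - infant
  outcome <- c(rep("live_birth", live), rep("stillbirth", stillbirths))
  death_window <- c(
    rep("early_neonatal", early), rep("neonatal", late_neonatal),
    rep("post_neonatal", post_neonatal), rep("none", survivors),
    rep("none", stillbirths)
  )
  hosp <- c(seq_len(live) <= hospital, rep(NA, stillbirths))
  n <- live + stillbirths
  prefix <- paste0(substr(arm, 1, 3), if (native) "_nat" else "_mig")
  tibble(
    record_id = sprintf("%s_%05d", prefix, seq_len(n)),
    cluster_id = sprintf("%s_phc_%02d", substr(arm, 1, 3),
                         ((seq_len(n) - 1L) %% n_clusters) + 1L),
    arm = arm,
    mother_native = native,
    outcome = outcome,
    death_window = death_window,
    hospital_delivery = hosp
  )
}

#' Reference surveillance records (trial outcome table, record level)
#'
#' A deterministic record-level dataset whose ITT and PP marginals equal
#' the trial's published outcome table in every cell: live births
#' 4059/4171 (control/intervention) ITT and 2740/3014 PP; infant deaths
#' 236/233 ITT and 184/170 PP; nested early-neonatal and neonatal counts;
#' stillbirths; and hospital-delivery percentages to one decimal place.
#' Births are spread round-robin over 11 clusters (primary health
#' centers) per arm. The within-stratum ordering of deaths and hospital
#' flags is arbitrary; only marginals are meaningful.
#'
#' @return a validated birth-record tibble (~8,400 rows).
#' @export
reference_surveillance <- function() {
  strata <- bind_rows(
    # arm, native: live, early, neonatal, infant, stillbirths, hospital
    expand_stratum("intervention", TRUE, 3014, 83, 104, 170, 72, 2324),
    expand_stratum("intervention", FALSE, 4171 - 3014, 113 - 83, 142 - 104,
                   233 - 170, 90 - 72, 3349 - 2324),
    expand_stratum("control", TRUE, 2740, 81, 102, 184, 79, 2214),
    expand_stratum("control", FALSE, 4059 - 2740, 106 - 81, 138 - 102,
                   236 - 184, 107 - 79, 3389 - 2214)
  )
  validate_birth_records(strata)
}

#' Reference cost-effectiveness parameters
#'
#' The evaluation's headline valuation inputs: annual incremental cost
#' US$163,841 (the figure every published ICER chains from; the cost
#' table's arm difference, 154,263, is also computable from
#' [reference_cost_ledger()] and both are surfaced by
#' [run_full_evaluation()]), life expectancy 68.35 years (2016), GDP per
#' capita US$1709 (2016), per-protocol analysis set, and the trial's 280
#' intervention-arm ASHAs for the descriptive cost-per-ASHA line.
#'
#' @param analysis_set `"PP"` (default) or `"ITT"`.
#' @return a [cea_parameters()] object.
#' @export
reference_cea_parameters <- function(analysis_set = "PP") {
  cea_parameters(
    incremental_cost_annual = 163841,
    life_expectancy = 68.35,
    gdp_per_capita = 1709,
    analysis_set = analysis_set,
    n_ashas = 280
  )
}
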