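#' Validate birth-level surveillance records
#'
#' A record is one registered pregnancy outcome: a live birth or a
#' stillbirth in a study cluster, with the mother's native-residence flag
#' (the basis of the per-protocol restriction) and, for live births that
#' died within the first year, the age window of death. Windows are stored
#' disjointly (`early_neonatal` < 7 d, `neonatal` 7-27 d, `post_neonatal`
#' 28-364 d) and accumulated into the nested counts (early neonatal
#' \eqn{\subseteq} neonatal \eqn{\subseteq} infant) only at reporting time,
#' so no death is ever double-counted. Stillbirths cannot carry a death
#' window.
#'
#' @param records data frame with columns `record_id`, `cluster_id`, `arm`,
#'   `mother_native`, `outcome`, `death_window` and optionally
#'   `hospital_delivery`.
#' @return the validated records as a tibble.
#' @export
validate_birth_records <- function(records) {
  records <- as_tibble(records)
  required <- c("record_id", "cluster_id", "arm", "mother_native",
                "outcome", "death_window")
  missing <- setdiff(required, names(records))
  if (length(missing) > 0) {
    abort(sprintf("surveillance records are missing column(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  if (nrow(records) == 0) {
    return(records)
  }
  records$arm <- tolower(as.character(records$arm))
  records$outcome <- tolower(as.character(records$outcome))
  records$death_window <- tolower(as.character(records$death_window))
  records$mother_native <- as.logical(records$mother_native)

  fail_rows <- function(bad, what, tokens = NULL) {
    if (any(bad)) {
      i <- which(bad)[1]
      tok <- if (!is.null(tokens)) sprintf(" (got '%s')", tokens[i]) else ""
      abort(sprintf("surveillance record row %d (id '%s'): %s%s.",
                    i, records$record_id[i], what, tok))
    }
  }
  fail_rows(duplicated(records$record_id), "duplicate record_id")
  fail_rows(!records$arm %in% ARMS, "unknown arm token", records$arm)
  fail_rows(!records$outcome %in% OUTCOMES, "unknown outcome token",
            records$outcome)
  fail_rows(!records$death_window %in% DEATH_WINDOWS,
            "unknown death_window token", records$death_window)
  fail_rows(is.na(records$mother_native), "mother_native must be TRUE/FALSE")
  fail_rows(records$outcome == "stillbirth" & records$death_window != "none",
            "a stillbirth cannot carry a death window", records$death_window)
  if ("hospital_delivery" %in% names(records)) {
    records$hospital_delivery <- as.logical(records$hospital_delivery)
  }
  records
}

count_one_arm <- function(records) {
  live <- records[records$outcome == "live_birth", , drop = FALSE]
  early <- sum(live$death_window == "early_neonatal")
  neo <- early + sum(live$death_window == "neonatal")
  infant <- neo + sum(live$death_window == "post_neonatal")
  tibble(
    live_births = nrow(live),
    early_neonatal_deaths = early,
    neonatal_deaths = neo,
    infant_deaths = infant,
    stillbirths = sum(records$outcome == "stillbirth")
  )
}

#' Build an analysis cohort from surveillance records
#'
#' The intention-to-treat (ITT) cohort counts every record; the
#' per-protocol (PP) cohort keeps only births to mothers native to the
#' study village, i.e. those fully exposed to their assigned arm (women
#' observing the custom of delivering at their maternal home are only
#' partially exposed and are excluded from PP). Death counts are reported
#' nested: neonatal deaths include early neonatal ones, infant deaths
#' include all neonatal ones.
#'
#' @param records validated birth records (see [validate_birth_records()]).
#' @param analysis_set `"ITT"` or `"PP"`.
#' @return a `cohort_counts` tibble with one row per arm and columns
#'   `analysis_set`, `arm`, `live_births`, `early_neonatal_deaths`,
#'   `neonatal_deaths`, `infant_deaths`, `stillbirths`.
#' @export
build_cohort <- function(records, analysis_set = "PP") {
  analysis_set <- match_analysis_set(analysis_set)
  records <- validate_birth_records(records)
  if (analysis_set == "PP" && nrow(records) > 0) {
    records <- records[records$mother_native, , drop = FALSE]
  }
  out <- lapply(ARMS, function(a) {
    counts <- count_one_arm(records[records$arm == a, , drop = FALSE])
    mutate(counts, analysis_set = analysis_set, arm = a, .before = 1)
  })
  res <- bind_rows(out)
  class(res) <- c("cohort_counts", class(res))
  res
}

cohort_arm <- function(counts, arm) {
  counts[counts$arm == arm, , drop = FALSE]
}

#' Mortality rate per 1000 live births
#'
#' @param events death count (0 to `live_births`).
#' @param live_births live-birth denominator, must be positive.
#' @return unrounded rate per 1000 live births; display convention is one
#'   decimal place.
#' @examples
#' rate_per_1000(170, 3014)  # 56.4 to 1 d.p.
#' @export
rate_per_1000 <- function(events, live_births) {
  assert_scalar_number(events, "events", min = 0)
  assert_scalar_number(live_births, "live_births", min = 0, strict_min = TRUE)
  if (events > live_births) {
    abort(sprintf("`events` (%s) cannot exceed `live_births` (%s).",
                  events, live_births))
  }
  1000 * events / live_births
}

#' Deaths averted per 1000 live births
#'
#' Control-arm rate minus intervention-arm rate; a negative value signals
#' harm rather than benefit.
#'
#' @param control_rate,intervention_rate rates per 1000 live births, each
#'   in `[0, 1000]`.
#' @return unrounded difference per 1000 live births.
#' @export
deaths_averted_per_1000 <- function(control_rate, intervention_rate) {
  assert_scalar_number(control_rate, "control_rate", min = 0)
  assert_scalar_number(intervention_rate, "intervention_rate", min = 0)
  if (control_rate > 1000 || intervention_rate > 1000) {
    abort("rates per 1000 live births cannot exceed 1000.")
  }
  control_rate - intervention_rate
}

#' Relative reduction in mortality (%)
#'
#' @inheritParams deaths_averted_per_1000
#' @return percentage reduction relative to the control rate.
#' @export
relative_reduction <- function(control_rate, intervention_rate) {
  assert_scalar_number(control_rate, "control_rate", min = 0, strict_min = TRUE)
  assert_scalar_number(intervention_rate, "intervention_rate", min = 0)
  100 * (control_rate - intervention_rate) / control_rate
}

#' Surveillance outcome table (ITT and PP, both arms)
#'
#' Tabulates live births, nested death counts, stillbirths and (when the
#' records carry a `hospital_delivery` flag) the hospital-delivery
#' percentage, for both analysis sets and both arms. The hospital-delivery
#' share is descriptive only and plays no part in the cost-effectiveness
#' chain.
#'
#' @param records validated birth records.
#' @return a tibble with one row per outcome variable and one column per
#'   analysis set x arm combination.
#' @export
outcome_table <- function(records) {
  records <- validate_birth_records(records)
  has_hosp <- "hospital_delivery" %in% names(records) && nrow(records) > 0
  cols <- list()
  for (set in ANALYSIS_SETS) {
    counts <- build_cohort(records, set)
    sub <- if (set == "PP" && nrow(records) > 0) {
      records[records$mother_native, , drop = FALSE]
    } else records
    for (a in c("control", "intervention")) {
      row <- cohort_arm(counts, a)
      col <- c(
        live_births = row$live_births,
        hospital_deliveries_pct = if (has_hosp) {
          arm_live <- sub[sub$arm == a & sub$outcome == "live_birth", ]
          if (nrow(arm_live) > 0) {
            100 * mean(arm_live$hospital_delivery, na.rm = TRUE)
          } else NA_real_
        } else NA_real_,
        early_neonatal_deaths = row$early_neonatal_deaths,
        neonatal_deaths = row$neonatal_deaths,
        stillbirths = row$stillbirths,
        infant_deaths = row$infant_deaths
      )
      cols[[paste(set, a, sep = "_")]] <- col
    }
  }
  out <- tibble(variable = names(cols[[1]]))
  for (nm in names(cols)) out[[nm]] <- unname(cols[[nm]])
  if (!has_hosp) {
    out <- out[out$variable != "hospital_deliveries_pct", , drop = FALSE]
  }
  out
}
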