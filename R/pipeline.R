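#' Read a full-evaluation run configuration
#'
#' YAML with the following keys, all optional unless noted. Inputs:
#' `ledger` (path to a cost ledger CSV) or `simulate_costs:
#' {jitter_fraction}`; `surveillance` (path to a records CSV) or
#' `simulate: {<trial_sim_config fields>}`; `seed`. Parameters (under
#' `params`): `incremental_cost_annual` (a number, or the string
#' `"ledger"` to use the ledger arm difference), `life_expectancy`,
#' `gdp_per_capita`, `analysis_set`, `n_ashas`, `lys_discount_rate`.
#' `policy`: annualization-policy overrides. `scenarios`: a list of named
#' scenario blocks with [scenario()] fields. `out_dir`: where to write
#' the report bundle.
#'
#' @param path YAML file.
#' @return the configuration list (class `run_config`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("run config '%s' does not exist.", path))
  }
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = c("run_config", "list"))
}

resolve_policy <- function(cfg) {
  pol <- cfg$policy
  annualization_policy(
    discount_rate = pol$discount_rate %||% 0.03,
    default_useful_life = if (!is.null(pol$default_useful_life)) {
      unlist(pol$default_useful_life)
    } else NULL,
    price_year = pol$price_year %||% "2016-2017"
  )
}

resolve_scenarios <- function(cfg) {
  lapply(cfg$scenarios, function(s) {
    do.call(scenario, s)
  })
}

#' Run the full economic evaluation
#'
#' Chains every stage: read (or simulate) the cost ledger and the
#' surveillance records, summarize annualized costs per arm and their
#' difference, build the ITT and PP cohorts and the outcome table,
#' compute the ICER panel for the chosen analysis set, run the scenario
#' sensitivity analysis, and locate the result on the cost-effectiveness
#' plane (both per 1000 live births and for the whole cohort). When
#' `out_dir` is set, the bundle is written out as delimited-text tables
#' plus a machine-readable JSON summary with provenance (input file
#' hashes, parameters, seed, package version, rounding conventions).
#'
#' With no explicit `incremental_cost_annual` in `params`, the ledger arm
#' difference is used; both the ledger difference and the figure actually
#' used are always reported, since program accounts and headline
#' evaluations can legitimately differ in what they include.
#'
#' @param config a `run_config` list (see [read_run_config()]) or a path
#'   to one.
#' @return the report bundle (class `evaluation_bundle`), invisibly when
#'   written to disk.
#' @export
run_full_evaluation <- function(config) {
  if (is.character(config)) {
    config <- read_run_config(config)
  }
  stopifnot(is.list(config))
  seed <- config$seed
  policy <- resolve_policy(config)
  provenance <- list(
    package_version = as.character(utils::packageVersion("ceapipe")),
    seed = seed,
    price_year = policy$price_year,
    discount_rate = policy$discount_rate,
    rounding = "dollars and life-years to integers, rates to 1 d.p.; all chaining unrounded",
    inputs = list()
  )

  # --- cost ledger -----------------------------------------------------
  ledger <- if (!is.null(config$ledger)) {
    provenance$inputs$ledger <- list(
      path = config$ledger,
      md5 = unname(tools::md5sum(config$ledger))
    )
    read_cost_ledger(config$ledger)
  } else if (!is.null(config$simulate_costs)) {
    jf <- config$simulate_costs$jitter_fraction %||% 0
    provenance$inputs$ledger <- list(simulated = TRUE, jitter_fraction = jf)
    bind_rows(
      simulate_cost_ledger(reference_cost_ledger("intervention"),
                           jitter_fraction = jf, seed = seed),
      reference_cost_ledger("control")
    )
  } else {
    provenance$inputs$ledger <- list(reference = TRUE)
    reference_cost_ledger("both")
  }
  costs_intervention <- summarize_costs(
    ledger[ledger$arm == "intervention", , drop = FALSE], "intervention", policy)
  costs_control <- summarize_costs(
    ledger[ledger$arm == "control", , drop = FALSE], "control", policy)
  ledger_incremental <- as.numeric(incremental_cost(costs_intervention,
                                                    costs_control))

  # --- surveillance ----------------------------------------------------
  records <- if (!is.null(config$surveillance)) {
    provenance$inputs$surveillance <- list(
      path = config$surveillance,
      md5 = unname(tools::md5sum(config$surveillance))
    )
    read_surveillance(config$surveillance)
  } else if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$seed <- sim_args$seed %||% seed
    provenance$inputs$surveillance <- c(list(simulated = TRUE), sim_args)
    simulate_surveillance(do.call(trial_sim_config, sim_args))
  } else {
    provenance$inputs$surveillance <- list(reference = TRUE)
    reference_surveillance()
  }
  outcomes <- outcome_table(records)
  cohort_itt <- build_cohort(records, "ITT")
  cohort_pp <- build_cohort(records, "PP")

  # --- CEA -------------------------------------------------------------
  p <- config$params
  inc_cost <- p$incremental_cost_annual %||% "ledger"
  inc_used <- if (identical(inc_cost, "ledger")) ledger_incremental else
    as.numeric(inc_cost)
  analysis_set <- match_analysis_set(p$analysis_set %||% "PP")
  params <- cea_parameters(
    incremental_cost_annual = inc_used,
    life_expectancy = p$life_expectancy %||% 68.35,
    gdp_per_capita = p$gdp_per_capita %||% 1709,
    analysis_set = analysis_set,
    n_ashas = p$n_ashas %||% NA_real_,
    lys_discount_rate = p$lys_discount_rate %||% 0
  )
  provenance$params <- params[c("incremental_cost_annual", "life_expectancy",
                                "gdp_per_capita", "analysis_set", "n_ashas",
                                "lys_discount_rate")]
  effect <- effect_from_cohort(
    if (analysis_set == "PP") cohort_pp else cohort_itt)
  panel <- icer_panel(params, effect)

  scen_list <- resolve_scenarios(config)
  scen_table <- scenario_table(params, effect, scen_list)

  # --- CE plane --------------------------------------------------------
  cohort_scale <- effect$live_births_intervention / 1000
  plane <- tibble(
    basis = c("per_1000_live_births", "whole_cohort"),
    delta_effect_lys = c(panel$lys_per_1000,
                         panel$lys_per_1000 * cohort_scale),
    delta_cost = c(panel$cost_per_1000_live_births,
                   panel$cost_per_1000_live_births * cohort_scale)
  )
  plane$quadrant <- vapply(seq_len(nrow(plane)), function(i) {
    q <- ce_plane_point(plane$delta_cost[i], plane$delta_effect_lys[i])$quadrant
    if (is.na(q)) NA_character_ else q
  }, character(1))

  bundle <- structure(
    list(
      ledger = ledger,
      costs_intervention = costs_intervention,
      costs_control = costs_control,
      ledger_incremental_cost = ledger_incremental,
      incremental_cost_used = inc_used,
      outcome_table = outcomes,
      cohort_itt = cohort_itt,
      cohort_pp = cohort_pp,
      effect = effect,
      panel = panel,
      scenario_table = scen_table,
      ce_plane = plane,
      provenance = provenance
    ),
    class = "evaluation_bundle"
  )

  if (!is.null(config$out_dir)) {
    write_bundle(bundle, config$out_dir)
    return(invisible(bundle))
  }
  bundle
}

cost_summary_table <- function(s) {
  tibble(
    arm = s$arm,
    category = names(s$by_category),
    annualized = unname(s$by_category),
    percent = unname(s$percent_by_item)
  )
}

#' Write an evaluation bundle to disk
#'
#' @param bundle an `evaluation_bundle` from [run_full_evaluation()].
#' @param out_dir output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_bundle <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "evaluation_bundle"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  f <- function(name) file.path(out_dir, name)
  readr::write_csv(bind_rows(cost_summary_table(bundle$costs_intervention),
                             cost_summary_table(bundle$costs_control)),
                   f("cost_summary.csv"), progress = FALSE)
  readr::write_csv(bundle$outcome_table, f("outcome_table.csv"),
                   progress = FALSE)
  readr::write_csv(bind_rows(bundle$cohort_itt, bundle$cohort_pp),
                   f("cohort_counts.csv"), progress = FALSE)
  readr::write_csv(bundle$scenario_table, f("scenario_table.csv"),
                   progress = FALSE)
  readr::write_csv(bundle$ce_plane, f("ce_plane.csv"), progress = FALSE)
  panel <- bundle$panel
  summary <- list(
    panel = panel[c("analysis_set", "incremental_cost_annual",
                    "live_births_intervention", "live_births_control",
                    "cost_per_live_birth", "cost_per_1000_live_births",
                    "deaths_averted_per_1000", "lys_per_1000",
                    "cost_per_death_averted", "cost_per_lys", "verdict")],
    ledger_incremental_cost = bundle$ledger_incremental_cost,
    incremental_cost_used = bundle$incremental_cost_used,
    provenance = bundle$provenance
  )
  jsonlite::write_json(summary, f("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(out_dir)
}

#' @export
print.evaluation_bundle <- function(x, ...) {
  cat("== Program costs ==\n")
  print(x$costs_intervention)
  print(x$costs_control)
  cat(sprintf("Ledger incremental cost: %s; used in CEA: %s\n\n",
              format(round_dollars(x$ledger_incremental_cost), big.mark = ","),
              format(round_dollars(x$incremental_cost_used), big.mark = ",")))
  cat("== Outcome table ==\n")
  print(x$outcome_table)
  cat("\n== ICER panel ==\n")
  print(x$panel)
  cat("\n== Scenarios ==\n")
  print(x$scenario_table, n = Inf)
  invisible(x)
}
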