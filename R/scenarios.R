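#' Define a sensitivity-analysis scenario
#'
#' A named deterministic perturbation of the reference case. The effect
#' side can be scaled (`effect_multiplier`, with 1 the observed effect) or
#' replaced outright (`deaths_averted_override`, per 1000 live births).
#' The cost side can come from one of three places: an explicit annual
#' incremental cost; a per-ASHA cost times the number of ASHAs (the
#' program's natural scale unit, one frontline worker per ~1000
#' population); or -- for scale-up settings whose full cost model lives
#' outside the evaluation -- an externally supplied cost per death averted
#' (`cost_per_death_averted_override`, quoted at 100% observed
#' effectiveness and rescaled by the effect multiplier). At most one cost
#' basis may be set; with none set the reference-case incremental cost is
#' reused.
#'
#' @param name unique scenario label.
#' @param effect_multiplier non-negative scale on the observed effect.
#' @param analysis_set `"ITT"` or `"PP"`.
#' @param incremental_cost_annual optional US$ per year.
#' @param cost_per_asha optional US$ per ASHA per year (requires
#'   `n_ashas`).
#' @param n_ashas optional positive count of ASHAs.
#' @param deaths_averted_override optional per-1000 effect replacing the
#'   base estimate (still scaled by `effect_multiplier`).
#' @param cost_per_death_averted_override optional US$ per death averted
#'   at 100% effectiveness.
#' @return an object of class `cea_scenario`.
#' @export
scenario <- function(name,
                     effect_multiplier = 1,
                     analysis_set = "PP",
                     incremental_cost_annual = NULL,
                     cost_per_asha = NULL,
                     n_ashas = NULL,
                     deaths_averted_override = NULL,
                     cost_per_death_averted_override = NULL) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    abort("`name` must be a non-empty string.")
  }
  assert_scalar_number(effect_multiplier, "effect_multiplier", min = 0)
  n_bases <- (!is.null(incremental_cost_annual)) + (!is.null(cost_per_asha)) +
    (!is.null(cost_per_death_averted_override))
  if (n_bases > 1) {
    abort(sprintf(
      "scenario '%s': set at most one cost basis (incremental_cost_annual, cost_per_asha, or cost_per_death_averted_override).",
      name
    ))
  }
  if (!is.null(cost_per_asha)) {
    assert_scalar_number(cost_per_asha, "cost_per_asha", min = 0)
    if (is.null(n_ashas)) {
      abort(sprintf("scenario '%s': `cost_per_asha` requires `n_ashas`.", name))
    }
    assert_scalar_number(n_ashas, "n_ashas", min = 0, strict_min = TRUE)
  }
  if (!is.null(incremental_cost_annual)) {
    assert_scalar_number(incremental_cost_annual, "incremental_cost_annual")
  }
  if (!is.null(deaths_averted_override)) {
    assert_scalar_number(deaths_averted_override, "deaths_averted_override")
  }
  if (!is.null(cost_per_death_averted_override)) {
    assert_scalar_number(cost_per_death_averted_override,
                         "cost_per_death_averted_override", min = 0)
  }
  structure(
    list(name = name, effect_multiplier = effect_multiplier,
         analysis_set = match_analysis_set(analysis_set),
         incremental_cost_annual = incremental_cost_annual,
         cost_per_asha = cost_per_asha, n_ashas = n_ashas,
         deaths_averted_override = deaths_averted_override,
         cost_per_death_averted_override = cost_per_death_averted_override),
    class = "cea_scenario"
  )
}

#' Annual incremental cost per ASHA
#'
#' @param incremental_cost_annual US$ per year.
#' @param n_ashas number of ASHAs delivering the program; positive.
#' @return US$ per ASHA per year.
#' @export
cost_per_asha <- function(incremental_cost_annual, n_ashas) {
  assert_scalar_number(incremental_cost_annual, "incremental_cost_annual")
  assert_scalar_number(n_ashas, "n_ashas", min = 0, strict_min = TRUE)
  incremental_cost_annual / n_ashas
}

#' Run one scenario against the reference case
#'
#' Scales the effect, resolves the scenario's cost basis, and recomputes
#' the full ICER panel. An identity scenario (multiplier 1, no overrides)
#' reproduces the reference result exactly. Halving the effect exactly
#' doubles the cost per death averted and per life-year saved
#' (pre-rounding), since every ratio is inversely proportional to the
#' effect.
#'
#' @param base_params reference-case [cea_parameters()].
#' @param base_effect reference-case [effect_estimate()].
#' @param s a [scenario()].
#' @return a `cea_result` with the scenario name in `$scenario`.
#' @export
run_scenario <- function(base_params, base_effect, s) {
  stopifnot(inherits(base_params, "cea_parameters"),
            inherits(base_effect, "effect_estimate"),
            inherits(s, "cea_scenario"))
  base_da <- if (!is.null(s$deaths_averted_override)) {
    s$deaths_averted_override
  } else {
    base_effect$deaths_averted_per_1000
  }
  da <- base_da * s$effect_multiplier
  eff <- effect_estimate(da, base_effect$live_births_intervention,
                         base_effect$live_births_control)

  params <- base_params
  params$analysis_set <- s$analysis_set
  if (!is.null(s$incremental_cost_annual)) {
    params$incremental_cost_annual <- s$incremental_cost_annual
  }
  if (!is.null(s$cost_per_asha)) {
    params$incremental_cost_annual <- s$cost_per_asha * s$n_ashas
    params$n_ashas <- s$n_ashas
  }

  if (!is.null(s$cost_per_death_averted_override)) {
    # External scale-up cost model: the cost per death averted is an input
    # (quoted at full effectiveness) and the panel is chained from it.
    undefined <- s$effect_multiplier == 0
    cpda <- if (undefined) NA_real_ else
      s$cost_per_death_averted_override / s$effect_multiplier
    lyd <- lys_per_death(params)
    cplys <- if (undefined) NA_real_ else cpda / lyd
    cp1000 <- if (undefined) NA_real_ else cpda * da
    verdict <- classify(cplys, params$gdp_per_capita,
                        if (undefined) 1 else sign(cpda), sign(da))
    res <- structure(
      list(
        analysis_set = params$analysis_set,
        incremental_cost_annual = NA_real_,
        live_births_intervention = eff$live_births_intervention,
        live_births_control = eff$live_births_control,
        cost_per_live_birth = cp1000 / 1000,
        cost_per_1000_live_births = cp1000,
        deaths_averted_per_1000 = da,
        lys_per_1000 = da * lyd,
        cost_per_death_averted = cpda,
        cost_per_lys = cplys,
        life_expectancy = params$life_expectancy,
        gdp_per_capita = params$gdp_per_capita,
        ratios_undefined = undefined,
        verdict = verdict
      ),
      class = "cea_result"
    )
  } else {
    res <- icer_panel(params, eff)
  }
  res$scenario <- s$name
  res$n_ashas <- if (!is.null(s$n_ashas)) s$n_ashas else params$n_ashas
  res
}

#' Scenario sensitivity-analysis table
#'
#' One block per scenario (the reference case first) with the report
#' rows in their conventional order: infant deaths averted, cost per
#' ASHA, cost per infant death averted, cost per life-year saved --
#' unrounded values alongside their display-rounded forms.
#'
#' @param base_params reference-case [cea_parameters()].
#' @param base_effect reference-case [effect_estimate()].
#' @param scenarios list of [scenario()] objects; names must be unique.
#' @return a tibble with columns `scenario`, `variable`, `value`,
#'   `displayed`.
#' @export
scenario_table <- function(base_params, base_effect, scenarios = list()) {
  stopifnot(is.list(scenarios))
  if (length(scenarios) > 0) {
    nms <- vapply(scenarios, function(s) {
      stopifnot(inherits(s, "cea_scenario"))
      s$name
    }, character(1))
    if (anyDuplicated(nms)) {
      abort(sprintf("duplicate scenario name(s): %s.",
                    paste(unique(nms[duplicated(nms)]), collapse = ", ")))
    }
  }
  reference <- run_scenario(base_params, base_effect,
                            scenario("Reference case",
                                     analysis_set = base_params$analysis_set))
  results <- c(list(reference),
               lapply(scenarios, function(s)
                 run_scenario(base_params, base_effect, s)))
  block <- function(res) {
    cpa <- if (!is.na(res$n_ashas) && !is.na(res$incremental_cost_annual)) {
      cost_per_asha(res$incremental_cost_annual, res$n_ashas)
    } else NA_real_
    tibble(
      scenario = res$scenario,
      variable = c("infant_deaths_averted_per_1000", "cost_per_asha",
                   "cost_per_death_averted", "cost_per_lys"),
      value = c(res$deaths_averted_per_1000, cpa,
                res$cost_per_death_averted, res$cost_per_lys),
      displayed = c(round_dollars(res$deaths_averted_per_1000),
                    round_dollars(cpa),
                    round_dollars(res$cost_per_death_averted),
                    round_dollars(res$cost_per_lys))
    )
  }
  bind_rows(lapply(results, block))
}
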