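#' Cost-effectiveness analysis parameters
#'
#' The valuation inputs of the evaluation: the annual incremental cost of
#' running the program (an explicit input, so that either a ledger-derived
#' difference or an externally reported figure can be used), the life
#' expectancy used to convert an averted infant death into life-years
#' saved, and the GDP-per-capita willingness-to-pay threshold. Life-years
#' saved are undiscounted by default, matching the convention of valuing a
#' full remaining life expectancy per averted infant death; setting
#' `lys_discount_rate > 0` instead values each averted death at the
#' discounted annuity of one life-year over the life expectancy.
#'
#' @param incremental_cost_annual US$ per year.
#' @param life_expectancy years of life gained per infant death averted.
#' @param gdp_per_capita US$ threshold for the cost-effectiveness verdict.
#' @param analysis_set `"ITT"` or `"PP"` (label carried into results).
#' @param n_ashas optional count of frontline health workers (ASHAs)
#'   delivering the program, used only for the cost-per-ASHA report line.
#' @param lys_discount_rate annual discount rate applied to life-years
#'   saved; `0` (the default) leaves them undiscounted.
#' @return an object of class `cea_parameters`.
#' @export
cea_parameters <- function(incremental_cost_annual,
                           life_expectancy = 68.35,
                           gdp_per_capita = 1709,
                           analysis_set = "PP",
                           n_ashas = NA_real_,
                           lys_discount_rate = 0) {
  assert_scalar_number(incremental_cost_annual, "incremental_cost_annual")
  assert_scalar_number(life_expectancy, "life_expectancy", min = 0,
                       strict_min = TRUE)
  assert_scalar_number(gdp_per_capita, "gdp_per_capita", min = 0,
                       strict_min = TRUE)
  assert_scalar_number(lys_discount_rate, "lys_discount_rate", min = 0)
  structure(
    list(
      incremental_cost_annual = as.numeric(incremental_cost_annual),
      life_expectancy = life_expectancy,
      gdp_per_capita = gdp_per_capita,
      analysis_set = match_analysis_set(analysis_set),
      n_ashas = n_ashas,
      lys_discount_rate = lys_discount_rate
    ),
    class = "cea_parameters"
  )
}

# Life-years credited per death averted under the parameters' discounting
# convention (full life expectancy when the rate is 0).
lys_per_death <- function(params) {
  if (params$lys_discount_rate > 0) {
    annuity_factor(params$lys_discount_rate, floor(params$life_expectancy))
  } else {
    params$life_expectancy
  }
}

#' Effect estimate: deaths averted with their denominators
#'
#' @param deaths_averted_per_1000 control minus intervention infant
#'   mortality rate, per 1000 live births.
#' @param live_births_intervention,live_births_control live-birth counts
#'   that produced the rates; both must be positive.
#' @return an object of class `effect_estimate`.
#' @export
effect_estimate <- function(deaths_averted_per_1000,
                            live_births_intervention,
                            live_births_control) {
  assert_scalar_number(deaths_averted_per_1000, "deaths_averted_per_1000")
  assert_scalar_number(live_births_intervention, "live_births_intervention",
                       min = 0, strict_min = TRUE)
  assert_scalar_number(live_births_control, "live_births_control",
                       min = 0, strict_min = TRUE)
  structure(
    list(deaths_averted_per_1000 = deaths_averted_per_1000,
         live_births_intervention = live_births_intervention,
         live_births_control = live_births_control),
    class = "effect_estimate"
  )
}

#' Effect estimate from cohort counts
#'
#' Convenience chain from a [build_cohort()] result: computes both arms'
#' infant mortality rates and their difference.
#'
#' @param counts a `cohort_counts` tibble.
#' @return an `effect_estimate` with the arm rates attached as
#'   `rate_control` and `rate_intervention`.
#' @export
effect_from_cohort <- function(counts) {
  stopifnot(inherits(counts, "cohort_counts"))
  ctl <- cohort_arm(counts, "control")
  int <- cohort_arm(counts, "intervention")
  rc <- rate_per_1000(ctl$infant_deaths, ctl$live_births)
  ri <- rate_per_1000(int$infant_deaths, int$live_births)
  eff <- effect_estimate(deaths_averted_per_1000(rc, ri),
                         int$live_births, ctl$live_births)
  eff$rate_control <- rc
  eff$rate_intervention <- ri
  eff
}

#' Life-years saved per 1000 live births
#'
#' Deaths averted multiplied by the life expectancy credited per averted
#' infant death (undiscounted full life expectancy in the reference
#' convention).
#'
#' @param deaths_averted_per_1000 per 1000 live births.
#' @param life_expectancy years.
#' @return life-years per 1000 live births, unrounded; displayed rounded
#'   to the nearest integer.
#' @examples
#' life_years_saved_per_1000(10.75, 68.35)  # 734.8, reported 735
#' @export
life_years_saved_per_1000 <- function(deaths_averted_per_1000,
                                      life_expectancy) {
  assert_scalar_number(deaths_averted_per_1000, "deaths_averted_per_1000")
  assert_scalar_number(life_expectancy, "life_expectancy", min = 0,
                       strict_min = TRUE)
  deaths_averted_per_1000 * life_expectancy
}

#' Incremental cost per 1000 live births
#'
#' Normalizes the annual incremental cost by the intervention arm's annual
#' live births (the costing denominator: the cost is incurred where the
#' program runs).
#'
#' @param incremental_cost_annual US$ per year.
#' @param live_births_intervention live births in the intervention arm.
#' @return US$ per 1000 live births.
#' @export
cost_per_1000_live_births <- function(incremental_cost_annual,
                                      live_births_intervention) {
  assert_scalar_number(incremental_cost_annual, "incremental_cost_annual")
  assert_scalar_number(live_births_intervention, "live_births_intervention",
                       min = 0, strict_min = TRUE)
  1000 * incremental_cost_annual / live_births_intervention
}

#' Cost-effectiveness verdict against a GDP threshold
#'
#' An intervention is `cost_effective` when it buys additional effect at a
#' cost per life-year saved strictly below GDP per capita; a tie is not
#' cost-effective. `dominant` means cheaper and more effective (no ratio
#' needed); `dominated` means costlier and less effective.
#'
#' @param cost_per_lys US$ per life-year saved (may be `NA` when the
#'   effect is zero).
#' @param gdp_per_capita US$ threshold.
#' @param delta_cost_sign,delta_effect_sign signs (-1, 0, +1) of the
#'   incremental cost and incremental effect.
#' @return one of `"cost_effective"`, `"not_cost_effective"`,
#'   `"dominated"`, `"dominant"`.
#' @export
classify <- function(cost_per_lys, gdp_per_capita,
                     delta_cost_sign, delta_effect_sign) {
  assert_scalar_number(gdp_per_capita, "gdp_per_capita", min = 0,
                       strict_min = TRUE)
  if (delta_cost_sign <= 0 && delta_effect_sign > 0) {
    return("dominant")
  }
  if (delta_cost_sign > 0 && delta_effect_sign < 0) {
    return("dominated")
  }
  if (delta_effect_sign > 0 && !is.na(cost_per_lys) &&
      cost_per_lys >= 0 && cost_per_lys < gdp_per_capita) {
    return("cost_effective")
  }
  "not_cost_effective"
}

#' The incremental cost-effectiveness panel
#'
#' Chains the incremental cost and the mortality effect into every ratio
#' of the evaluation: cost per live birth and per 1000 live births, deaths
#' averted and life-years saved per 1000 live births, cost per infant
#' death averted, cost per life-year saved, and the threshold verdict. All
#' chaining uses unrounded values; the print method applies the display
#' conventions (dollars and life-years to integers, rates to one decimal).
#' When the effect is zero the ratio fields are `NA` and flagged
#' undefined, with the verdict taken from the cost-effectiveness plane
#' quadrant alone.
#'
#' @param params a [cea_parameters()] object.
#' @param effect an [effect_estimate()].
#' @return an object of class `cea_result`.
#' @examples
#' params <- cea_parameters(incremental_cost_annual = 163841)
#' effect <- effect_estimate(10.75, 3014, 2740)
#' icer_panel(params, effect)
#' @export
icer_panel <- function(params, effect) {
  stopifnot(inherits(params, "cea_parameters"),
            inherits(effect, "effect_estimate"))
  da <- effect$deaths_averted_per_1000
  cp1000 <- cost_per_1000_live_births(params$incremental_cost_annual,
                                      effect$live_births_intervention)
  lyd <- lys_per_death(params)
  lys1000 <- da * lyd
  undefined <- da == 0
  cpda <- if (undefined) NA_real_ else cp1000 / da
  cplys <- if (undefined) NA_real_ else cpda / lyd
  verdict <- classify(cplys, params$gdp_per_capita,
                      sign(params$incremental_cost_annual), sign(da))
  structure(
    list(
      analysis_set = params$analysis_set,
      incremental_cost_annual = params$incremental_cost_annual,
      live_births_intervention = effect$live_births_intervention,
      live_births_control = effect$live_births_control,
      cost_per_live_birth = cp1000 / 1000,
      cost_per_1000_live_births = cp1000,
      deaths_averted_per_1000 = da,
      lys_per_1000 = lys1000,
      cost_per_death_averted = cpda,
      cost_per_lys = cplys,
      life_expectancy = params$life_expectancy,
      gdp_per_capita = params$gdp_per_capita,
      ratios_undefined = undefined,
      verdict = verdict
    ),
    class = "cea_result"
  )
}

#' @export
print.cea_result <- function(x, ...) {
  cat(sprintf("Cost-effectiveness panel (%s analysis)\n", x$analysis_set))
  fmt <- function(v) format(round_dollars(v), big.mark = ",")
  cat(sprintf("  Annual incremental cost (US$)        %10s\n",
              fmt(x$incremental_cost_annual)))
  cat(sprintf("  Live births, intervention arm (n)    %10s\n",
              fmt(x$live_births_intervention)))
  cat(sprintf("  Cost per live birth (US$)            %10s\n",
              fmt(x$cost_per_live_birth)))
  cat(sprintf("  Cost per 1000 live births (US$)      %10s\n",
              fmt(x$cost_per_1000_live_births)))
  cat(sprintf("  Infant deaths averted per 1000 (n)   %10s\n",
              fmt(x$deaths_averted_per_1000)))
  cat(sprintf("  Life years saved per 1000 (LE %.2f)  %9s\n",
              x$life_expectancy, fmt(x$lys_per_1000)))
  if (x$ratios_undefined) {
    cat("  Cost per death averted / per LYS:  undefined (zero effect)\n")
  } else {
    cat(sprintf("  Cost per infant death averted (US$)  %10s\n",
                fmt(x$cost_per_death_averted)))
    cat(sprintf("  Cost per life year saved (US$)       %10s\n",
                fmt(x$cost_per_lys)))
  }
  cat(sprintf("  Verdict vs GDP per capita %s: %s\n",
              format(x$gdp_per_capita, big.mark = ","), x$verdict))
  invisible(x)
}

#' Locate a point on the cost-effectiveness plane
#'
#' The plane plots incremental effect on the x-axis against incremental
#' cost on the y-axis. Quadrants: NE (costlier, more effective -- a
#' trade-off judged by the threshold), SE (cheaper, more effective --
#' dominant), NW (costlier, less effective -- dominated), SW (cheaper,
#' less effective). A point on an axis or at the origin has no quadrant.
#'
#' @param delta_cost incremental cost, US$.
#' @param delta_effect incremental effect, life-years (or any effect unit).
#' @return list with `delta_effect`, `delta_cost` and `quadrant` (one of
#'   `"NE"`, `"NW"`, `"SE"`, `"SW"`, or `NA` on an axis).
#' @export
ce_plane_point <- function(delta_cost, delta_effect) {
  assert_scalar_number(delta_cost, "delta_cost")
  assert_scalar_number(delta_effect, "delta_effect")
  quadrant <- if (delta_cost == 0 || delta_effect == 0) {
    NA_character_
  } else if (delta_effect > 0) {
    if (delta_cost > 0) "NE" else "SE"
  } else {
    if (delta_cost > 0) "NW" else "SW"
  }
  list(delta_effect = delta_effect, delta_cost = delta_cost,
       quadrant = quadrant)
}
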