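#' Minimal two-arm decision tree
#'
#' The evaluation's decision model: a chance tree in which every live
#' birth in an arm either dies in infancy (probability `p`) or survives,
#' with an arm-specific program cost attached to each live birth. Averting
#' a death credits the full shared life expectancy. This is the smallest
#' tree that reproduces the direct incremental analysis, and evaluating it
#' is an independent route to the same ICERs.
#'
#' @param p_death_control,p_death_intervention probability of infant death
#'   per live birth, in `[0, 1]`.
#' @param cost_per_live_birth_control,cost_per_live_birth_intervention
#'   program cost attached to each live birth, US$.
#' @param life_expectancy years credited per averted death.
#' @return an object of class `two_arm_decision_tree`.
#' @export
two_arm_decision_tree <- function(p_death_control, p_death_intervention,
                                  cost_per_live_birth_control,
                                  cost_per_live_birth_intervention,
                                  life_expectancy = 68.35) {
  for (nm in c("p_death_control", "p_death_intervention")) {
    p <- get(nm)
    assert_scalar_number(p, nm, min = 0)
    if (p > 1) abort(sprintf("`%s` must be a probability in [0, 1].", nm))
  }
  assert_scalar_number(cost_per_live_birth_control,
                       "cost_per_live_birth_control")
  assert_scalar_number(cost_per_live_birth_intervention,
                       "cost_per_live_birth_intervention")
  assert_scalar_number(life_expectancy, "life_expectancy", min = 0,
                       strict_min = TRUE)
  structure(
    list(p_death_control = p_death_control,
         p_death_intervention = p_death_intervention,
         cost_per_live_birth_control = cost_per_live_birth_control,
         cost_per_live_birth_intervention = cost_per_live_birth_intervention,
         life_expectancy = life_expectancy),
    class = "two_arm_decision_tree"
  )
}

#' Evaluate the two-arm decision tree
#'
#' Rolls the tree forward over a cohort of live births per arm: expected
#' deaths are `p * births`, expected arm cost is the per-birth cost times
#' births, and the incremental quantities are their arm differences.
#' Life-years saved are the expected deaths averted times the shared life
#' expectancy. When parameterized from the same inputs, the resulting
#' ICERs equal those of [icer_panel()] (an equivalence exercised in the
#' test suite).
#'
#' @param tree a [two_arm_decision_tree()].
#' @param births_per_arm live births entering each arm.
#' @return list with expected `deaths_control`, `deaths_intervention`,
#'   `deaths_averted`, `incremental_cost`, `lys`, `cost_per_death_averted`
#'   and `cost_per_lys` (the two ratios are `NA` when the arms are equally
#'   effective).
#' @export
evaluate_decision_tree <- function(tree, births_per_arm) {
  stopifnot(inherits(tree, "two_arm_decision_tree"))
  assert_scalar_number(births_per_arm, "births_per_arm", min = 0,
                       strict_min = TRUE)
  deaths_c <- tree$p_death_control * births_per_arm
  deaths_i <- tree$p_death_intervention * births_per_arm
  averted <- deaths_c - deaths_i
  dcost <- (tree$cost_per_live_birth_intervention -
              tree$cost_per_live_birth_control) * births_per_arm
  lys <- averted * tree$life_expectancy
  list(
    deaths_control = deaths_c,
    deaths_intervention = deaths_i,
    deaths_averted = averted,
    incremental_cost = dcost,
    lys = lys,
    cost_per_death_averted = if (averted == 0) NA_real_ else dcost / averted,
    cost_per_lys = if (lys == 0) NA_real_ else dcost / lys
  )
}
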