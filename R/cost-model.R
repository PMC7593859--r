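#' Construct a cost ledger line item
#'
#' One priced resource in the program's cost ledger. `amount` is the
#' undiscounted one-time outlay for capital items and the annual recurrent
#' outlay otherwise. Capital items must carry a useful life either here or
#' through the policy's per-category defaults.
#'
#' @param label free-text description.
#' @param category one of the ledger categories (see `cost_categories()`).
#' @param phase `"start_up"` or `"implementation"`.
#' @param arm `"intervention"` or `"control"`.
#' @param amount US$, non-negative.
#' @param is_capital logical; capital items are annualized.
#' @param useful_life_years positive integer, required for capital items
#'   with no category default.
#' @return a one-row tibble with the ledger schema.
#' @export
cost_line_item <- function(label, category, phase, arm, amount,
                           is_capital = FALSE, useful_life_years = NA_real_) {
  validate_cost_ledger(tibble(
    label = as.character(label), category = as.character(category),
    phase = as.character(phase), arm = as.character(arm),
    amount = as.numeric(amount), is_capital = as.logical(is_capital),
    useful_life_years = as.numeric(useful_life_years)
  ))
}

#' Ledger category tokens
#' @return character vector of recognised cost categories.
#' @export
cost_categories <- function() COST_CATEGORIES

#' Validate a cost ledger
#'
#' Checks the schema and row-level invariants of a cost ledger: known
#' category/phase/arm tokens, non-negative amounts, and a useful life of at
#' least one year on any capital item that states one. Failures name the
#' offending row.
#'
#' @param items data frame with columns `label`, `category`, `phase`,
#'   `arm`, `amount`, `is_capital` and optionally `useful_life_years`.
#' @return the validated ledger as a tibble (invisible errors otherwise).
#' @export
validate_cost_ledger <- function(items) {
  items <- as_tibble(items)
  required <- c("label", "category", "phase", "arm", "amount", "is_capital")
  missing <- setdiff(required, names(items))
  if (length(missing) > 0) {
    abort(sprintf("cost ledger is missing column(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  if (!"useful_life_years" %in% names(items)) {
    items$useful_life_years <- NA_real_
  }
  items$useful_life_years <- as.numeric(items$useful_life_years)
  items$amount <- as.numeric(items$amount)
  items$is_capital <- as.logical(items$is_capital)
  for (i in seq_len(nrow(items))) {
    row <- items[i, ]
    where <- sprintf("cost ledger row %d ('%s')", i, row$label)
    if (!row$category %in% COST_CATEGORIES) {
      abort(sprintf("%s: unknown category '%s'.", where, row$category))
    }
    if (!row$phase %in% COST_PHASES) {
      abort(sprintf("%s: unknown phase '%s'.", where, row$phase))
    }
    if (!row$arm %in% ARMS) {
      abort(sprintf("%s: unknown arm '%s'.", where, row$arm))
    }
    if (is.na(row$amount) || row$amount < 0) {
      abort(sprintf("%s: amount must be a non-negative number (got %s).",
                    where, row$amount))
    }
    if (is.na(row$is_capital)) {
      abort(sprintf("%s: is_capital must be TRUE or FALSE.", where))
    }
    if (isTRUE(row$is_capital) && !is.na(row$useful_life_years) &&
        row$useful_life_years < 1) {
      abort(sprintf("%s: useful_life_years must be >= 1 for capital items.",
                    where))
    }
    if (!isTRUE(row$is_capital) && !is.na(row$useful_life_years)) {
      abort(sprintf("%s: useful_life_years is only meaningful for capital items.",
                    where))
    }
  }
  items
}

#' Summarize annualized program costs for one arm
#'
#' Annualizes every ledger item and aggregates by category and by phase
#' (start-up vs implementation), producing the arm's grand total and the
#' percentage share of each category. The summary is deterministic under
#' any permutation of the input rows; an empty ledger yields an all-zero
#' summary rather than an error.
#'
#' @param items cost ledger tibble; all rows must belong to `arm`.
#' @param arm `"intervention"` or `"control"`.
#' @param policy an [annualization_policy()].
#' @return an object of class `cost_summary` with fields `arm`,
#'   `by_category`, `phase_totals`, `grand_total`, `percent_by_item` and
#'   `price_year`.
#' @export
summarize_costs <- function(items, arm, policy = annualization_policy()) {
  assert_choice(arm, "arm", ARMS)
  stopifnot(inherits(policy, "annualization_policy"))
  items <- validate_cost_ledger(items)
  if (nrow(items) > 0 && !all(items$arm == arm)) {
    bad <- which(items$arm != arm)[1]
    abort(sprintf(
      "cost ledger row %d belongs to arm '%s', not the requested '%s'.",
      bad, items$arm[bad], arm
    ))
  }
  ann <- annualize_ledger(items, policy)
  by_category <- setNames(numeric(length(COST_CATEGORIES)), COST_CATEGORIES)
  phase_totals <- setNames(numeric(length(COST_PHASES)), COST_PHASES)
  if (nrow(ann) > 0) {
    cat_sum <- tapply(ann$annualized, ann$category, sum)
    by_category[names(cat_sum)] <- cat_sum
    ph_sum <- tapply(ann$annualized, ann$phase, sum)
    phase_totals[names(ph_sum)] <- ph_sum
  }
  grand_total <- sum(by_category)
  percent_by_item <- if (grand_total > 0) 100 * by_category / grand_total else
    by_category * 0
  structure(
    list(arm = arm, by_category = by_category, phase_totals = phase_totals,
         grand_total = grand_total, percent_by_item = percent_by_item,
         price_year = policy$price_year),
    class = "cost_summary"
  )
}

#' @export
print.cost_summary <- function(x, ...) {
  cat(sprintf("Annualized program costs, %s arm (US$, %s prices)\n",
              x$arm, x$price_year))
  nz <- x$by_category[x$by_category > 0]
  if (length(nz) == 0) {
    cat("  (empty ledger)\n")
  } else {
    for (nm in names(nz)) {
      cat(sprintf("  %-22s %10s  (%.1f%%)\n", nm,
                  format(round_dollars(nz[[nm]]), big.mark = ","),
                  x$percent_by_item[[nm]]))
    }
  }
  cat(sprintf("  start-up total       %10s\n",
              format(round_dollars(x$phase_totals[["start_up"]]), big.mark = ",")))
  cat(sprintf("  implementation total %10s\n",
              format(round_dollars(x$phase_totals[["implementation"]]), big.mark = ",")))
  cat(sprintf("  grand total          %10s\n",
              format(round_dollars(x$grand_total), big.mark = ",")))
  invisible(x)
}

#' Incremental annual cost of the intervention
#'
#' Difference between the intervention and control arms' annualized grand
#' totals; negative values mean the intervention is cheaper. If the two
#' summaries carry different price-year labels the difference is still
#' returned, with the mismatch recorded both as an R warning and in the
#' result's `price_year_mismatch` attribute.
#'
#' @param intervention,control `cost_summary` objects for the two arms.
#' @return incremental cost in US$ per year (scalar, attributes
#'   `price_year` and `price_year_mismatch`).
#' @export
incremental_cost <- function(intervention, control) {
  stopifnot(inherits(intervention, "cost_summary"),
            inherits(control, "cost_summary"))
  if (intervention$arm != "intervention" || control$arm != "control") {
    abort("`incremental_cost()` expects an intervention summary then a control summary.")
  }
  mismatch <- !identical(intervention$price_year, control$price_year)
  if (mismatch) {
    warn(sprintf(
      "price-year mismatch: intervention at '%s', control at '%s'.",
      intervention$price_year, control$price_year
    ))
  }
  structure(
    intervention$grand_total - control$grand_total,
    price_year = intervention$price_year,
    price_year_mismatch = mismatch
  )
}
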