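#' Annuity factor for capital-cost annualization
#'
#' Present value of a unit payment stream in arrears over `n_years` at a
#' constant annual discount rate: `AF = sum_{t=1..n} (1 + r)^-t`, which has
#' the closed form `(1 - (1 + r)^-n) / r` and the analytic limit `AF = n`
#' at `r = 0`. A one-time capital outlay divided by this factor gives its
#' equivalent annual cost over its useful life.
#'
#' @param rate annual discount rate as a fraction (e.g. `0.03` for 3%).
#'   Must be non-negative.
#' @param n_years useful life in whole years; positive integer.
#' @return the dimensionless annuity factor, a positive scalar.
#' @examples
#' annuity_factor(0.03, 10)  # 8.530203
#' annuity_factor(0, 5)      # 5: zero-discount limit
#' @export
annuity_factor <- function(rate, n_years) {
  assert_scalar_number(rate, "rate", min = 0)
  assert_scalar_number(n_years, "n_years", min = 1)
  if (n_years != as.integer(n_years)) {
    abort(sprintf("`n_years` must be a whole number of years (got %s).", n_years))
  }
  if (rate == 0) {
    return(as.numeric(n_years))
  }
  # -expm1(-n*log1p(r))/r is the closed form rewritten to stay accurate as
  # r -> 0, where the naive (1-(1+r)^-n)/r cancels catastrophically
  -expm1(-n_years * log1p(rate)) / rate
}

#' Annualization policy: discount rate and default useful lives
#'
#' Bundles the discount rate, the per-category default useful lives used
#' when a capital line item does not state its own, and the price-year
#' label under which all amounts are expressed. Defaults follow standard
#' program-costing assumptions for mHealth community-health programs:
#' software builds and four-wheelers last 10 years, two-wheelers 7,
#' IT equipment 5, mobile handsets 3, and one-time orientation training is
#' treated as a capital investment with a 3-year life (refresher training,
#' by contrast, is a recurrent annual activity and is never annualized).
#'
#' @param discount_rate annual discount rate, fraction per year.
#' @param default_useful_life named numeric vector mapping cost categories
#'   to useful lives in years; merged over the built-in defaults.
#' @param price_year label for the price year of all amounts.
#' @return an object of class `annualization_policy`.
#' @export
annualization_policy <- function(discount_rate = 0.03,
                                 default_useful_life = NULL,
                                 price_year = "2016-2017") {
  assert_scalar_number(discount_rate, "discount_rate", min = 0)
  lives <- c(
    software_development = 10, vehicle_four_wheeler = 10,
    vehicle_two_wheeler = 7, it_equipment = 5, mobile_handset = 3,
    training_orientation = 3
  )
  if (!is.null(default_useful_life)) {
    if (is.null(names(default_useful_life)) ||
        !all(names(default_useful_life) %in% COST_CATEGORIES)) {
      abort("`default_useful_life` must be named by known cost categories.")
    }
    if (any(default_useful_life < 1)) {
      abort("`default_useful_life`: all useful lives must be >= 1 year.")
    }
    lives[names(default_useful_life)] <- default_useful_life
  }
  structure(
    list(discount_rate = discount_rate, default_useful_life = lives,
         price_year = as.character(price_year)),
    class = "annualization_policy"
  )
}

#' @export
print.annualization_policy <- function(x, ...) {
  cat("Annualization policy\n")
  cat(sprintf("  discount rate: %.1f%% per year\n", 100 * x$discount_rate))
  cat(sprintf("  price year:    %s\n", x$price_year))
  cat("  default useful lives (years):\n")
  for (nm in names(x$default_useful_life)) {
    cat(sprintf("    %-22s %d\n", nm, as.integer(x$default_useful_life[[nm]])))
  }
  invisible(x)
}

resolve_useful_life <- function(category, useful_life_years, policy) {
  if (!is.na(useful_life_years)) {
    return(useful_life_years)
  }
  if (category %in% names(policy$default_useful_life)) {
    return(unname(policy$default_useful_life[[category]]))
  }
  NA_real_
}

#' Annualize a single cost line item
#'
#' Capital items are converted to an equivalent annual cost by dividing the
#' one-time outlay by the discounted annuity factor over the item's useful
#' life (taken from the item itself, else from the policy's per-category
#' defaults). Recurrent (non-capital) items already represent an annual
#' outlay and pass through unchanged.
#'
#' @param item a one-row cost ledger tibble (see [cost_line_item()]).
#' @param policy an [annualization_policy()].
#' @return annualized cost in US$ per year (scalar).
#' @examples
#' pol <- annualization_policy()
#' it <- cost_line_item("laptops", "it_equipment", "start_up",
#'                      "intervention", 1000, is_capital = TRUE,
#'                      useful_life_years = 5)
#' annualize_item(it, pol)  # 1000 / 4.579707 = 218.35
#' @export
annualize_item <- function(item, policy = annualization_policy()) {
  stopifnot(inherits(policy, "annualization_policy"))
  item <- validate_cost_ledger(item)
  if (nrow(item) != 1L) {
    abort("`annualize_item()` expects a single line item; see `annualize_ledger()`.")
  }
  if (!item$is_capital) {
    return(item$amount)
  }
  life <- resolve_useful_life(item$category, item$useful_life_years, policy)
  if (is.na(life)) {
    abort(sprintf(
      "capital item '%s' (category '%s') has no useful life and no policy default.",
      item$label, item$category
    ))
  }
  item$amount / annuity_factor(policy$discount_rate, life)
}

#' Annualize every item in a cost ledger
#'
#' @param items a cost ledger tibble.
#' @param policy an [annualization_policy()].
#' @return the ledger with an `annualized` column (US$ per year).
#' @export
annualize_ledger <- function(items, policy = annualization_policy()) {
  items <- validate_cost_ledger(items)
  ann <- vapply(seq_len(nrow(items)), function(i) {
    annualize_item(items[i, , drop = FALSE], policy)
  }, numeric(1))
  mutate(items, annualized = ann)
}
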