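COST_LEDGER_COLS <- c("label", "category", "phase", "arm", "amount",
                      "is_capital", "useful_life_years")
SURVEILLANCE_COLS <- c("record_id", "cluster_id", "arm", "mother_native",
                       "outcome", "death_window")

check_header <- function(path, found, required, optional = character()) {
  missing <- setdiff(required, found)
  if (length(missing) > 0) {
    abort(sprintf("'%s': missing required column(s): %s.", path,
                  paste(missing, collapse = ", ")))
  }
  extra <- setdiff(found, c(required, optional))
  if (length(extra) > 0) {
    abort(sprintf("'%s': unrecognised column(s): %s.", path,
                  paste(extra, collapse = ", ")))
  }
}

#' Read a cost ledger from delimited text
#'
#' Comma-separated, UTF-8, one row per line item, header row with the
#' exact field names `label, category, phase, arm, amount, is_capital,
#' useful_life_years` (the last may be omitted entirely for ledgers with
#' no capital items). Every row is validated; the first malformed row is
#' reported with its row number and label.
#'
#' @param path file path.
#' @return a validated cost ledger tibble.
#' @export
read_cost_ledger <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("cost ledger file '%s' does not exist.", path))
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  check_header(path, names(raw), setdiff(COST_LEDGER_COLS, "useful_life_years"),
               optional = "useful_life_years")
  if (nrow(raw) == 0) {
    return(validate_cost_ledger(tibble(
      label = character(), category = character(), phase = character(),
      arm = character(), amount = numeric(), is_capital = logical(),
      useful_life_years = numeric()
    )))
  }
  amount <- suppressWarnings(as.numeric(raw$amount))
  if (anyNA(amount)) {
    i <- which(is.na(amount))[1]
    abort(sprintf("'%s' row %d: amount '%s' is not a number.",
                  path, i, raw$amount[i]))
  }
  capital <- toupper(trimws(raw$is_capital)) %in% c("TRUE", "T", "1", "YES")
  life <- if ("useful_life_years" %in% names(raw)) {
    suppressWarnings(as.numeric(raw$useful_life_years))
  } else NA_real_
  validate_cost_ledger(tibble(
    label = raw$label, category = tolower(trimws(raw$category)),
    phase = tolower(trimws(raw$phase)), arm = tolower(trimws(raw$arm)),
    amount = amount, is_capital = capital, useful_life_years = life
  ))
}

#' Write a cost ledger to delimited text
#'
#' @param items validated cost ledger tibble.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_cost_ledger <- function(items, path) {
  items <- validate_cost_ledger(items)
  readr::write_csv(items[, COST_LEDGER_COLS], path, progress = FALSE)
  invisible(path)
}

#' Read surveillance records from delimited text
#'
#' Comma-separated, UTF-8, one row per birth record, header `record_id,
#' cluster_id, arm, mother_native, outcome, death_window` with an
#' optional `hospital_delivery` column. Enumeration tokens are
#' case-normalized; structural violations (unknown tokens, a stillbirth
#' carrying a death window) are rejected with the offending row.
#'
#' @param path file path.
#' @return a validated birth-record tibble.
#' @export
read_surveillance <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("surveillance file '%s' does not exist.", path))
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  check_header(path, names(raw), SURVEILLANCE_COLS,
               optional = "hospital_delivery")
  if (nrow(raw) == 0) {
    out <- tibble(record_id = character(), cluster_id = character(),
                  arm = character(), mother_native = logical(),
                  outcome = character(), death_window = character())
    return(validate_birth_records(out))
  }
  raw$mother_native <- toupper(trimws(raw$mother_native)) %in%
    c("TRUE", "T", "1", "YES")
  if ("hospital_delivery" %in% names(raw)) {
    hd <- toupper(trimws(raw$hospital_delivery))
    raw$hospital_delivery <- ifelse(hd %in% c("", "NA"), NA,
                                    hd %in% c("TRUE", "T", "1", "YES"))
  }
  validate_birth_records(raw)
}

#' Write surveillance records to delimited text
#'
#' @param records validated birth-record tibble.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_surveillance <- function(records, path) {
  records <- validate_birth_records(records)
  cols <- c(SURVEILLANCE_COLS,
            intersect("hospital_delivery", names(records)))
  readr::write_csv(records[, cols], path, progress = FALSE)
  invisible(path)
}

#' Read an annualization policy from a YAML config file
#'
#' Keys `discount_rate`, `price_year` and a nested `default_useful_life`
#' mapping (category -> years) override the built-in defaults; absent
#' keys keep them.
#'
#' @param path YAML file.
#' @return an [annualization_policy()].
#' @export
read_annualization_policy <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("policy file '%s' does not exist.", path))
  }
  cfg <- yaml::read_yaml(path)
  defaults <- annualization_policy()
  lives <- if (!is.null(cfg$default_useful_life)) {
    unlist(cfg$default_useful_life)
  } else NULL
  annualization_policy(
    discount_rate = cfg$discount_rate %||% defaults$discount_rate,
    default_useful_life = lives,
    price_year = cfg$price_year %||% defaults$price_year
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
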