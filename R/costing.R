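# Component micro-costing of the index intervention and sector-level
# follow-up costs, with annual-bucket discounting of late periods.
#
# All ledger arithmetic is kept at exact pence precision; unit prices are
# entirely configuration. The default table shipped with the package is a
# plausible synthetic stand-in for a 2018/2019 NHS price year, clearly
# non-authoritative.

#' The default (synthetic) unit-cost table
#'
#' Reads `inst/extdata/unit_costs_synthetic.csv`: per-minute staff and
#' theatre rates, device list prices, anaesthesia drug costs, ward and
#' catheter costs, and primary/secondary care contact prices. Values are
#' plausible for a 2018/2019 UK price year but are synthetic
#' configuration, not a published costing source.
#'
#' @return a `unit_cost_table`.
#' @export
default_unit_costs <- function() {
  path <- system.file("extdata", "unit_costs_synthetic.csv",
                      package = "trialcea")
  if (path == "")  # during development, before installation
    path <- file.path("inst", "extdata", "unit_costs_synthetic.csv")
  read_unit_costs(path)
}

#' Read a unit-cost table from CSV
#'
#' @param path CSV with columns `item`, `unit`, `price`, `source`.
#' @return a `unit_cost_table` object.
#' @export
read_unit_costs <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_that(all(c("item", "unit", "price", "source") %in% names(tab)),
             "unit cost file", "needs columns item, unit, price, source")
  check_that(all(tab$price >= 0), "price", "unit prices must be >= 0")
  check_that(!anyDuplicated(tab$item), "item", "duplicate resource items")
  structure(tab, class = c("unit_cost_table", "data.frame"))
}

#' Look up a unit price
#'
#' @param unit_costs a `unit_cost_table`.
#' @param item resource item code.
#' @return price in GBP.
#' @export
unit_price <- function(unit_costs, item) {
  i <- match(item, unit_costs$item)
  if (anyNA(i))
    stop(sprintf("unknown resource code(s): %s",
                 paste(item[is.na(i)], collapse = ", ")))
  unit_costs$price[i]
}

#' Micro-cost the index intervention for one patient
#'
#' Sums staff time (surgeon, anaesthetist when present, theatre nurses --
#' by default two band-five and one band-four -- all priced per minute of
#' theatre time), theatre overhead per minute, device list price, the
#' drug cost of the anaesthesia type, recovery time, hospital stay,
#' catheters, any return to theatre, and consumables.
#'
#' @param record one row of a trial dataset's `intervention` table (or a
#'   list with the same fields).
#' @param unit_costs a `unit_cost_table`.
#' @return cost in GBP at pence precision.
#' @export
cost_intervention <- function(record, unit_costs) {
  r <- as.list(record)
  check_that(r$theatre_minutes >= 0 && r$recovery_minutes >= 0 &&
               r$los_days >= 0, "times", "times and stay must be >= 0")
  per_min <- unit_price(unit_costs, "surgeon_per_min") +
    (if (isTRUE(r$anaesthetist_present))
       unit_price(unit_costs, "anaesthetist_per_min") else 0) +
    r$n_nurse_band5 * unit_price(unit_costs, "nurse_band5_per_min") +
    r$n_nurse_band4 * unit_price(unit_costs, "nurse_band4_per_min") +
    unit_price(unit_costs, "theatre_per_min")
  device <- if (is.na(r$device_type) || r$device_count == 0) 0 else
    r$device_count * unit_price(unit_costs, paste0("device_", r$device_type))
  drugs <- if (is.na(r$anaesthesia) || r$anaesthesia == "none") 0 else
    unit_price(unit_costs, paste0("anaesthesia_", r$anaesthesia))
  cons <- if (is.null(r$consumables_cost) || is.na(r$consumables_cost)) 0 else
    r$consumables_cost
  pence(r$theatre_minutes * per_min + device + drugs +
          r$recovery_minutes * unit_price(unit_costs, "recovery_per_min") +
          r$los_days * unit_price(unit_costs, "ward_day") +
          r$catheters * unit_price(unit_costs, "catheter") +
          (if (isTRUE(r$return_theatre))
             unit_price(unit_costs, "return_to_theatre") else 0) +
          cons)
}

#' Cost one follow-up period for one patient
#'
#' Multiplies resource-use counts by unit prices and sums per sector.
#' A "no" answer is recorded as a zero count and costs zero; an
#' unanswered questionnaire (missing counts) leaves the sector cost
#' missing, to be handled by multiple imputation.
#'
#' @param counts data frame with columns `item`, `count` for one patient
#'   and period (counts may be `NA`).
#' @param unit_costs a `unit_cost_table`.
#' @param period one of `"3m"`, `"15m"`, `"24m"`, `"36m"`.
#' @return named numeric `c(primary=, secondary=)`, possibly `NA`.
#' @export
cost_followup <- function(counts, unit_costs, period) {
  check_that(period %in% COST_PERIODS, "period",
             sprintf("must be one of %s", paste(COST_PERIODS, collapse = ", ")))
  check_that(all(counts$count >= 0, na.rm = TRUE), "count",
             "resource counts must be >= 0")
  sector_cost <- function(items) {
    rows <- counts[counts$item %in% items, ]
    if (nrow(rows) == 0L) return(0)
    if (anyNA(rows$count)) return(NA_real_)
    pence(sum(rows$count * unit_price(unit_costs, rows$item)))
  }
  c(primary = sector_cost(PRIMARY_ITEMS),
    secondary = sector_cost(SECONDARY_ITEMS))
}

#' Build the per-patient cost ledger for a trial dataset
#'
#' One row per patient: intervention cost (zero if surgery was not
#' received) and primary/secondary care cost per follow-up period.
#' Period costs from unanswered questionnaires are `NA`.
#'
#' @param dataset a `trial_dataset`.
#' @param unit_costs a `unit_cost_table`.
#' @return a `cost_ledger` data frame with columns `id`, `cost_int`,
#'   `pri_<period>` and `sec_<period>`.
#' @export
cost_ledger <- function(dataset, unit_costs = default_unit_costs()) {
  p <- dataset$patients
  iv <- dataset$intervention
  int_cost <- rep(0, nrow(p))
  if (nrow(iv)) {
    ic <- vapply(seq_len(nrow(iv)), function(i)
      cost_intervention(iv[i, ], unit_costs), numeric(1))
    int_cost[match(iv$id, p$id)] <- ic
  }
  led <- data.frame(id = p$id, cost_int = int_cost,
                    stringsAsFactors = FALSE)
  ru <- dataset$resource_use
  for (period in COST_PERIODS) {
    rp <- ru[ru$period == period, ]
    m <- vapply(p$id, function(pid)
      cost_followup(rp[rp$id == pid, ], unit_costs, period), numeric(2))
    led[[paste0("pri_", period)]] <- m["primary", ]
    led[[paste0("sec_", period)]] <- m["secondary", ]
  }
  rownames(led) <- NULL
  structure(led, class = c("cost_ledger", "data.frame"))
}

#' Total discounted cost per patient
#'
#' Intervention plus 3- and 15-month period costs undiscounted; costs in
#' the 24-month period multiplied by `(1 + r)^-1` and the 36-month
#' period by `(1 + r)^-2` (periods assigned to discount years by their
#' questionnaire label). `NA` period costs propagate.
#'
#' @param ledger a `cost_ledger`.
#' @param r annual discount rate (default 0.035).
#' @return numeric vector of per-patient totals (GBP).
#' @export
total_discounted_cost <- function(ledger, r = 0.035) {
  check_that(is.numeric(r) && r >= 0, "r", "must be >= 0")
  d1 <- (1 + r)^-1
  d2 <- (1 + r)^-2
  pence(ledger$cost_int +
          ledger$pri_3m + ledger$sec_3m +
          ledger$pri_15m + ledger$sec_15m +
          d1 * (ledger$pri_24m + ledger$sec_24m) +
          d2 * (ledger$pri_36m + ledger$sec_36m))
}

#' Zero-cost rule for unoperated patients without follow-up data
#'
#' Patients who did not receive surgery and returned no follow-up
#' resource-use data are assumed to have incurred zero secondary-care
#' costs (they never re-engaged with hospital services). With
#' `relax = TRUE` the assumption is dropped and their secondary costs
#' stay missing, to be multiply imputed (sensitivity analysis).
#'
#' @param ledger a `cost_ledger`.
#' @param patients the `patients` table of the trial dataset.
#' @param relax logical; default `FALSE` applies the zero-cost rule.
#' @return the modified `cost_ledger`.
#' @export
apply_no_surgery_cost_rule <- function(ledger, patients, relax = FALSE) {
  sec_cols <- paste0("sec_", COST_PERIODS)
  pri_cols <- paste0("pri_", COST_PERIODS)
  no_crf <- rowSums(!is.na(ledger[c(sec_cols, pri_cols)])) == 0L
  no_surg <- !patients$surgery_received[match(ledger$id, patients$id)]
  target <- no_surg & no_crf
  if (!relax && any(target)) ledger[target, sec_cols] <- 0
  ledger
}
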