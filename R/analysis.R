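# From a trial dataset to the per-patient analysis table and the pooled
# adjusted incremental cost and QALY estimates.

#' Build the per-patient analysis table
#'
#' Values every questionnaire response with the tariff/mapping, costs
#' every resource-use record, applies the no-surgery zero-cost rule, and
#' assembles one row per patient: baseline covariates, EQ-5D-3L
#' utilities per time point (`u_*`), condition-specific utilities
#' (`q_*`), the intervention cost and per-period sector costs. Missing
#' questionnaires stay `NA`; these are the multiple-imputation targets.
#'
#' @param dataset a `trial_dataset`.
#' @param unit_costs a `unit_cost_table`.
#' @param tariff EQ-5D-3L `utility_tariff`.
#' @param iciq_mapping condition-specific `utility_tariff`.
#' @param relax_no_surgery_rule passed to [apply_no_surgery_cost_rule()].
#' @return an `analysis_table` data frame.
#' @export
build_analysis_table <- function(dataset,
                                 unit_costs = default_unit_costs(),
                                 tariff = eq5d_tariff_uk(),
                                 iciq_mapping = iciq_mapping_synthetic(),
                                 relax_no_surgery_rule = FALSE) {
  p <- dataset$patients
  tab <- data.frame(id = p$id, arm = p$arm, centre = p$centre, age = p$age,
                    pfmt = p$pfmt, ui_type = p$ui_type,
                    surgery_received = p$surgery_received,
                    surgery_day = p$surgery_day, stringsAsFactors = FALSE)
  e <- dataset$eq5d
  for (tp in EQ5D_TIMES) {
    rows <- e[e$time == tp, ]
    u <- value_eq5d(rows[EQ5D_DIMENSIONS], tariff)
    tab[[paste0("u_", tp)]] <- u[match(p$id, rows$id)]
  }
  q <- dataset$iciq
  for (tp in ICIQ_TIMES) {
    rows <- q[q$time == tp, ]
    v <- value_iciq(rows[paste0("item", 1:8)], iciq_mapping)
    tab[[paste0("q_", tp)]] <- v[match(p$id, rows$id)]
  }
  led <- cost_ledger(dataset, unit_costs)
  led <- apply_no_surgery_cost_rule(led, p, relax = relax_no_surgery_rule)
  stopifnot(identical(led$id, tab$id))
  tab <- cbind(tab, led[setdiff(names(led), "id")])
  structure(tab, class = c("analysis_table", "data.frame"))
}

# Column groups used as imputation targets.
utility_cols <- function(prefix = "u_") paste0(prefix, EQ5D_TIMES[-1])
cost_cols <- function() as.vector(outer(c("pri_", "sec_"), COST_PERIODS,
                                        paste0))

#' Derive total discounted cost and QALYs on a completed analysis table
#'
#' Adds `total_cost` (discounted, [total_discounted_cost()] convention)
#' and `qaly` / `qaly_iciq` (discounted area under the utility curve,
#' [qaly_auc()]) columns. On tables with remaining missing values the
#' derived quantities are `NA` for the affected patients.
#'
#' @param tab an `analysis_table`.
#' @param options a [qaly_options()].
#' @param utility_source `"eq5d"` or `"iciq"`: which instrument feeds
#'   the `qaly` column used by the models.
#' @return the table with `total_cost` and `qaly` columns added.
#' @export
derive_outcomes <- function(tab, options = qaly_options(),
                            utility_source = "eq5d") {
  check_that(utility_source %in% c("eq5d", "iciq"), "utility_source",
             "must be eq5d or iciq")
  ledger_like <- tab[c("id", "cost_int", cost_cols())]
  tab$total_cost <- total_discounted_cost(
    structure(ledger_like, class = c("cost_ledger", "data.frame")),
    r = options$discount_rate)

  qaly_one <- function(i, prefix, times) {
    days <- if (prefix == "u_") eq5d_schedule_days(tab$surgery_day[i]) else
      c(baseline = 0, `3m` = ifelse(is.na(tab$surgery_day[i]), NA_real_,
                                    tab$surgery_day[i] + 91),
        `15m` = 456, `24m` = 730, `36m` = 1096)
    u <- unlist(tab[i, paste0(prefix, times)], use.names = FALSE)
    keep <- !is.na(days)
    if (!any(!is.na(u[keep]))) return(NA_real_)
    d <- days[keep]; uu <- pmin(u[keep], 1)
    # a late surgery can interleave the surgery-anchored and
    # randomisation-anchored points: integrate in time order, first
    # point winning on (rare) exact ties
    o <- order(d)
    d <- d[o]; uu <- uu[o]
    first <- !duplicated(d)
    tr <- utility_trajectory(d[first], uu[first],
                             surgery_day = tab$surgery_day[i],
                             id = tab$id[i])
    qaly_auc(tr, options)
  }
  tab$qaly_eq5d <- vapply(seq_len(nrow(tab)), qaly_one, numeric(1),
                          prefix = "u_", times = EQ5D_TIMES)
  tab$qaly_iciq <- vapply(seq_len(nrow(tab)), qaly_one, numeric(1),
                          prefix = "q_", times = ICIQ_TIMES)
  tab$qaly <- if (utility_source == "eq5d") tab$qaly_eq5d else tab$qaly_iciq
  tab
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Arm-difference estimator for completed data
#'
#' The full adjusted-GLM incremental-mean procedure on one completed
#' analysis table: fits the cost model (family/link as specified) and
#' the QALY model (Gaussian, identity) with the baseline-utility, PFMT
#' and age covariates, clustered by centre, and returns the recycled-
#' prediction incremental cost and QALY.
#'
#' @param tab completed analysis table with `total_cost` and `qaly`.
#' @param cost_family,cost_link family and link for the cost model.
#' @param baseline_var baseline quality-of-life adjustment covariate
#'   (`"u_baseline"`, or `"q_baseline"` for the condition-specific
#'   sensitivity analysis).
#' @return named numeric `c(delta_cost=, delta_qaly=)`.
#' @export
incremental_estimator <- function(tab, cost_family = "gaussian",
                                  cost_link = "identity",
                                  baseline_var = "u_baseline") {
  covs <- c(baseline_var, "pfmt", "age")
  fc <- fit_glm(tab, "total_cost", covs, cost_family, cost_link)
  fq <- fit_glm(tab, "qaly", covs, "gaussian", "identity")
  c(delta_cost = recycled_difference(fc), delta_qaly = recycled_difference(fq))
}

#' Impute an analysis table
#'
#' Runs predictive-mean-matching multiple imputation over the utility
#' and period-cost columns, with the complete baseline covariates as
#' predictors; within each group, completed variables join the
#' predictor set of later ones.
#'
#' @param tab an `analysis_table`.
#' @param m,knn,seed,proper see [impute_pmm()].
#' @param include_iciq impute the condition-specific utilities too.
#' @return an `imputation_set` of completed analysis tables.
#' @export
impute_analysis_table <- function(tab, m = 20L, knn = 5L, seed = 1L,
                                  proper = TRUE, include_iciq = TRUE) {
  targets <- list(eq5d = utility_cols("u_"), cost = cost_cols())
  if (include_iciq) targets$iciq <- paste0("q_", ICIQ_TIMES)
  targets <- lapply(targets, function(v) v[vapply(v, function(x)
    anyNA(tab[[x]]), logical(1))])
  targets <- targets[lengths(targets) > 0]
  if (length(targets) == 0L)
    return(structure(list(imputations = list(tab), m = 1L, knn = knn,
                          seed = seed, proper = proper, targets = list(),
                          predictors = character(0)),
                     class = "imputation_set"))
  # q_baseline can itself be missing only if the baseline questionnaire
  # failed validation upstream; baseline is complete by design
  preds <- c("arm", "age", "pfmt", "u_baseline", "ui_type")
  impute_pmm(tab, targets, preds, m = m, knn = knn, seed = seed,
             proper = proper)
}
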