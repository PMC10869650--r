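# Cost-effectiveness analysis: bootstrap joint distribution of
# incremental costs and QALYs, ICER/dominance classification, net
# monetary benefit and acceptability curves, and the sensitivity suite.

#' Net monetary benefit
#'
#' @param delta_cost incremental cost (GBP).
#' @param delta_qaly incremental QALYs.
#' @param lambda willingness to pay per QALY (>= 0); vectorised.
#' @return `lambda * delta_qaly - delta_cost`.
#' @export
nmb <- function(delta_cost, delta_qaly, lambda) {
  check_that(all(lambda >= 0), "lambda", "willingness to pay must be >= 0")
  lambda * delta_qaly - delta_cost
}

#' ICER and dominance classification
#'
#' Classifies the cost-effectiveness plane quadrant of an incremental
#' cost/QALY pair. Cheaper and more effective: the comparator is
#' dominated and no ratio is reported. Costlier and less effective: the
#' intervention is dominated. Northeast: cost per QALY gained.
#' Southwest: the ratio is reported as cost saving per QALY lost, where
#' a ratio above the willingness-to-pay threshold favours the
#' intervention.
#'
#' @param delta_cost incremental cost (intervention minus comparator).
#' @param delta_qaly incremental QALYs.
#' @return list with `value` (GBP per QALY, `NA` when dominance or an
#'   undefined ratio applies), `label`, and `quadrant` (`"NE"`, `"NW"`,
#'   `"SE"`, `"SW"`).
#' @export
icer <- function(delta_cost, delta_qaly) {
  if (delta_qaly == 0) {
    return(list(value = NA_real_,
                label = "ratio undefined; report cost difference only",
                quadrant = if (delta_cost >= 0) "N" else "S"))
  }
  quadrant <- paste0(if (delta_cost >= 0) "N" else "S",
                     if (delta_qaly > 0) "E" else "W")
  if (delta_cost < 0 && delta_qaly > 0)
    return(list(value = NA_real_, label = "comparator dominated",
                quadrant = quadrant))
  if (delta_cost >= 0 && delta_qaly < 0)
    return(list(value = NA_real_, label = "intervention dominated",
                quadrant = quadrant))
  ratio <- delta_cost / delta_qaly
  label <- if (delta_cost >= 0) sprintf("GBP %.0f per QALY gained", ratio)
           else sprintf("GBP %.0f cost saving per QALY lost", ratio)
  list(value = ratio, label = label, quadrant = quadrant)
}

#' Bootstrap the joint incremental cost/QALY distribution
#'
#' Non-parametric bootstrap combined with multiple imputation in a
#' single loop: each replicate samples one completed dataset uniformly,
#' resamples centres (clusters) with replacement, runs the estimator
#' and records the incremental pair. Replicates whose estimator fails
#' are dropped (aborting if more than 5% fail).
#'
#' @param imputations list of completed analysis tables (with outcomes
#'   derived), or an `imputation_set` already passed through
#'   [derive_outcomes()].
#' @param B number of bootstrap replicates.
#' @param seed integer seed.
#' @param estimator function(table) returning
#'   `c(delta_cost=, delta_qaly=)`; see [incremental_estimator()].
#' @param resample `"centre"` (default) resamples clusters;
#'   `"patient"` resamples patients.
#' @return a `cea_draws` object: data frame of `replicate`,
#'   `delta_cost`, `delta_qaly`, `imputation`.
#' @export
bootstrap_cea <- function(imputations, B = 2000L, seed = 1L,
                          estimator = incremental_estimator,
                          resample = c("centre", "patient")) {
  resample <- match.arg(resample)
  check_that(B >= 1, "B", "must be >= 1")
  if (inherits(imputations, "imputation_set"))
    imputations <- imputations$imputations
  check_that(length(imputations) >= 1, "imputations", "need at least one")
  draws <- with_seed(substream_seed(seed, "bootstrap"), {
    lapply(seq_len(B), function(b) {
      im <- sample.int(length(imputations), 1L)
      tab <- imputations[[im]]
      tb <- if (resample == "centre") resample_centres(tab) else
        tab[sample.int(nrow(tab), nrow(tab), replace = TRUE), ]
      est <- tryCatch(estimator(tb), error = function(e) NULL)
      if (is.null(est)) return(NULL)
      data.frame(replicate = b, delta_cost = unname(est[1]),
                 delta_qaly = unname(est[2]), imputation = im)
    })
  })
  failed <- sum(vapply(draws, is.null, logical(1)))
  if (failed > 0.05 * B)
    stop(sprintf("bootstrap aborted: %d of %d replicates failed", failed, B))
  if (failed > 0)
    message(sprintf("bootstrap: %d of %d replicates failed and were dropped",
                    failed, B))
  out <- do.call(rbind, draws[!vapply(draws, is.null, logical(1))])
  rownames(out) <- NULL
  structure(out, class = c("cea_draws", "data.frame"), seed = seed, B = B)
}

resample_centres <- function(tab) {
  centres <- unique(tab$centre)
  pick <- sample(centres, length(centres), replace = TRUE)
  out <- do.call(rbind, lapply(seq_along(pick), function(j) {
    d <- tab[tab$centre == pick[j], , drop = FALSE]
    d$centre <- paste0("bs", j)
    d
  }))
  rownames(out) <- NULL
  out
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the probability the intervention
#' is cost-effective is the fraction of bootstrap draws with positive
#' net monetary benefit; the comparator curve is the exact complement.
#'
#' @param draws a `cea_draws` object (or data frame with `delta_cost`,
#'   `delta_qaly`).
#' @param wtp_grid numeric vector of willingness-to-pay values.
#' @return data frame `lambda`, `p_intervention`, `p_comparator`.
#' @export
ceac <- function(draws, wtp_grid = default_wtp_grid()) {
  check_that(length(wtp_grid) >= 1, "wtp_grid", "must be non-empty")
  check_that(nrow(draws) >= 1, "draws", "need at least one draw")
  p <- vapply(wtp_grid, function(l)
    mean(nmb(draws$delta_cost, draws$delta_qaly, l) > 0), numeric(1))
  data.frame(lambda = wtp_grid, p_intervention = p, p_comparator = 1 - p)
}

#' @rdname ceac
#' @export
default_wtp_grid <- function() {
  sort(unique(c(seq(0, 50000, by = 500), 20000, 30000)))
}

quadrant_proportions <- function(draws) {
  q <- paste0(ifelse(draws$delta_cost >= 0, "N", "S"),
              ifelse(draws$delta_qaly > 0, "E", "W"))
  tab <- table(factor(q, levels = c("NE", "NW", "SE", "SW")))
  out <- as.numeric(tab) / nrow(draws)
  names(out) <- names(tab)
  out
}

#' Run the full cost-utility analysis on a trial dataset
#'
#' Orchestrates the base-case pipeline: valuation and costing into the
#' analysis table, missingness diagnosis, multiple imputation (when
#' more than 5% of cost or QALY data are missing and `mi = TRUE`),
#' outcome derivation, cost-model family/link selection, per-imputation
#' adjusted incremental means pooled by Rubin's rules, and the
#' bootstrap cost-effectiveness plane, ICER and acceptability curve.
#'
#' @param dataset a `trial_dataset`.
#' @param mi use multiple imputation (`FALSE` = complete-case).
#' @param m,knn number of imputations and donors.
#' @param B bootstrap replicates.
#' @param seed master seed (imputation and bootstrap substreams are
#'   derived from it).
#' @param discount_rate annual discount rate for costs and QALYs.
#' @param adjust_surgery_wait hold utility flat until surgery.
#' @param utility_source `"eq5d"` or `"iciq"`.
#' @param relax_no_surgery_rule sensitivity switch for the zero-cost
#'   rule.
#' @param select_cost_model run [select_family_link()] for the cost
#'   model (otherwise Gaussian/identity).
#' @param wtp_grid willingness-to-pay grid for the CEAC.
#' @param unit_costs,tariff,iciq_mapping configuration tables.
#' @return a `cea_result`: pooled incremental estimates with CIs,
#'   per-arm adjusted means, ICER/dominance, CEAC, quadrant
#'   proportions, draws, and the settings used.
#' @export
run_cua <- function(dataset, mi = TRUE, m = 20L, knn = 5L, B = 2000L,
                    seed = 1L, discount_rate = 0.035,
                    adjust_surgery_wait = TRUE, utility_source = "eq5d",
                    relax_no_surgery_rule = FALSE,
                    select_cost_model = TRUE,
                    wtp_grid = default_wtp_grid(),
                    unit_costs = default_unit_costs(),
                    tariff = eq5d_tariff_uk(),
                    iciq_mapping = iciq_mapping_synthetic()) {
  opts <- qaly_options(discount_rate = discount_rate,
                       adjust_surgery_wait = adjust_surgery_wait)
  tab <- build_analysis_table(dataset, unit_costs, tariff, iciq_mapping,
                              relax_no_surgery_rule = relax_no_surgery_rule)
  vars <- c(utility_cols("u_"), cost_cols())
  # the 4-week and 3-month questionnaires exist only for operated
  # patients; for the others they are structurally absent, not missing
  eligible <- list(u_4w = tab$surgery_received, u_3m = tab$surgery_received)
  report <- missingness_model(tab, vars = vars, eligible = eligible)
  mi_triggered <- isTRUE(attr(report, "mi_triggered"))

  baseline_var <- if (utility_source == "eq5d") "u_baseline" else "q_baseline"
  completed <- if (mi && mi_triggered) {
    imp <- impute_analysis_table(tab, m = m, knn = knn, seed = seed,
                                 include_iciq = utility_source == "iciq")
    lapply(imp$imputations, derive_outcomes, options = opts,
           utility_source = utility_source)
  } else {
    one <- derive_outcomes(tab, options = opts,
                           utility_source = utility_source)
    list(one[!is.na(one$total_cost) & !is.na(one$qaly), ])
  }

  # cost model family/link; candidates needing positivity are dropped
  # when zero totals occur (possible for unoperated patients)
  y1 <- completed[[1]]$total_cost
  cand <- default_candidates()
  if (any(y1 <= 0))
    cand <- cand[!cand$family %in% c("Gamma", "inverse.gaussian"), ]
  sel <- if (select_cost_model) {
    s <- select_family_link(completed[[1]], "total_cost",
                            covariates = c(baseline_var, "pfmt", "age"),
                            candidates = cand)
    list(family = s$family, link = s$link, table = s$decision_table,
         lambda = s$lambda)
  } else list(family = "gaussian", link = "identity", table = NULL,
              lambda = NA_real_)

  covs <- c(baseline_var, "pfmt", "age")
  per_imp <- lapply(completed, function(ti) {
    fc <- fit_glm(ti, "total_cost", covs, sel$family, sel$link)
    fq <- fit_glm(ti, "qaly", covs, "gaussian", "identity")
    list(dc = recycled_difference(fc), vc = delta_variance(fc),
         dq = recycled_difference(fq), vq = delta_variance(fq),
         mc = adjusted_arm_means(fc), mq = adjusted_arm_means(fq))
  })
  pool_c <- rubins_pool(vapply(per_imp, `[[`, numeric(1), "dc"),
                        vapply(per_imp, `[[`, numeric(1), "vc"))
  pool_q <- rubins_pool(vapply(per_imp, `[[`, numeric(1), "dq"),
                        vapply(per_imp, `[[`, numeric(1), "vq"))
  arm_means <- list(
    cost = rowMeans(vapply(per_imp, `[[`, numeric(2), "mc")),
    qaly = rowMeans(vapply(per_imp, `[[`, numeric(2), "mq")))

  estimator <- function(ti) incremental_estimator(
    ti, cost_family = sel$family, cost_link = sel$link,
    baseline_var = baseline_var)
  draws <- bootstrap_cea(completed, B = B, seed = seed,
                         estimator = estimator)
  curve <- ceac(draws, wtp_grid)
  ic <- icer(pool_c$estimate, pool_q$estimate)

  structure(list(
    delta_cost = pool_c, delta_qaly = pool_q, arm_means = arm_means,
    icer = ic, ceac = curve, quadrants = quadrant_proportions(draws),
    draws = draws, missingness = report, mi_used = mi && mi_triggered,
    n_analysed = nrow(completed[[1]]),
    cost_model = sel, settings = list(
      mi = mi, m = m, knn = knn, B = B, seed = seed,
      discount_rate = discount_rate,
      adjust_surgery_wait = adjust_surgery_wait,
      utility_source = utility_source,
      relax_no_surgery_rule = relax_no_surgery_rule)
  ), class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  p_at <- function(l) x$ceac$p_intervention[match(l, x$ceac$lambda)]
  cat("<cea_result>\n")
  cat(sprintf("  n analysed: %d (%s)\n", x$n_analysed,
              if (x$mi_used) sprintf("multiple imputation, m = %d",
                                     x$settings$m) else "complete case"))
  cat(sprintf("  cost model: %s family, %s link\n",
              x$cost_model$family, x$cost_model$link))
  cat(sprintf("  incremental cost:  GBP %.0f [%.0f, %.0f]\n",
              x$delta_cost$estimate, x$delta_cost$ci[1], x$delta_cost$ci[2]))
  cat(sprintf("  incremental QALYs: %.3f [%.3f, %.3f]\n",
              x$delta_qaly$estimate, x$delta_qaly$ci[1], x$delta_qaly$ci[2]))
  cat(sprintf("  ICER: %s\n", x$icer$label))
  cat(sprintf("  P(cost-effective) at GBP 0 / 20k / 30k: %.0f%% / %.0f%% / %.0f%%\n",
              100 * p_at(0), 100 * p_at(20000), 100 * p_at(30000)))
  invisible(x)
}

#' Run the base case and the five sensitivity analyses
#'
#' Emits one row per analysis in the shape of a published incremental
#' cost-effectiveness table: adjusted per-arm costs and QALYs, pooled
#' incremental cost and QALYs with CIs, ICER or dominance label, and
#' the probability the intervention is cost-effective at GBP 0, 20 000
#' and 30 000 per QALY. Variants: (1) complete case, (2) no
#' surgery-wait adjustment, (3) condition-specific utilities, (4) 6%
#' discount rate, (5) relaxed zero-cost rule for unoperated patients
#' without follow-up data. A failed variant is reported and the others
#' continue.
#'
#' @param dataset a `trial_dataset`.
#' @param ... passed to [run_cua()] (e.g. `m`, `B`, `seed`).
#' @return a `sensitivity_suite`: list with `table` (data frame) and
#'   `results` (named list of `cea_result` / error messages).
#' @export
run_sensitivity_suite <- function(dataset, ...) {
  variants <- list(
    base_case = list(),
    complete_case = list(mi = FALSE),
    no_surgery_wait_adjustment = list(adjust_surgery_wait = FALSE),
    iciq_utilities = list(utility_source = "iciq"),
    discount_6pct = list(discount_rate = 0.06),
    relax_no_surgery_cost_rule = list(relax_no_surgery_rule = TRUE)
  )
  dots <- list(...)
  results <- lapply(names(variants), function(nm) {
    args <- utils::modifyList(dots, variants[[nm]])
    tryCatch(do.call(run_cua, c(list(dataset), args)),
             error = function(e) sprintf("failed: %s", conditionMessage(e)))
  })
  names(results) <- names(variants)
  rows <- lapply(names(results), function(nm) {
    r <- results[[nm]]
    if (!inherits(r, "cea_result"))
      return(data.frame(analysis = nm, error = as.character(r),
                        stringsAsFactors = FALSE))
    p_at <- function(l) r$ceac$p_intervention[match(l, r$ceac$lambda)]
    data.frame(
      analysis = nm,
      cost_intervention = round(r$arm_means$cost[["intervention"]]),
      cost_comparator = round(r$arm_means$cost[["comparator"]]),
      delta_cost = round(r$delta_cost$estimate),
      delta_cost_lo = round(r$delta_cost$ci[1]),
      delta_cost_hi = round(r$delta_cost$ci[2]),
      qaly_intervention = round(r$arm_means$qaly[["intervention"]], 3),
      qaly_comparator = round(r$arm_means$qaly[["comparator"]], 3),
      delta_qaly = round(r$delta_qaly$estimate, 3),
      delta_qaly_lo = round(r$delta_qaly$ci[1], 3),
      delta_qaly_hi = round(r$delta_qaly$ci[2], 3),
      icer = r$icer$label,
      p_ce_0 = round(r$ceac$p_intervention[match(0, r$ceac$lambda)], 2),
      p_ce_20000 = round(p_at(20000), 2),
      p_ce_30000 = round(p_at(30000), 2),
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, lapply(rows, function(d) {
    # align columns across success/failure rows
    all_cols <- c("analysis", "cost_intervention", "cost_comparator",
                  "delta_cost", "delta_cost_lo", "delta_cost_hi",
                  "qaly_intervention", "qaly_comparator", "delta_qaly",
                  "delta_qaly_lo", "delta_qaly_hi", "icer",
                  "p_ce_0", "p_ce_20000", "p_ce_30000", "error")
    for (cc in setdiff(all_cols, names(d))) d[[cc]] <- NA
    d[all_cols]
  }))
  structure(list(table = tab, results = results),
            class = "sensitivity_suite")
}

#' @export
print.sensitivity_suite <- function(x, ...) {
  cat("<sensitivity_suite>\n")
  print(x$table[c("analysis", "delta_cost", "delta_qaly", "icer",
                  "p_ce_20000")])
  invisible(x)
}
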