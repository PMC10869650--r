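# Missingness diagnosis, multiple imputation by predictive mean
# matching, and pooling by Rubin's rules.

#' Diagnose the missingness mechanism of an analysis table
#'
#' For each analysis variable with missing values, fits a logistic
#' regression of the missing indicator on age, the minimisation
#' covariates (PFMT, baseline utility), baseline urinary-incontinence
#' type and arm, and reports the fraction missing and the fitted
#' coefficients with p-values. Multiple imputation is flagged as
#' triggered when more than 5% of any cost or QALY variable is missing.
#'
#' @param data an analysis table (see [build_analysis_table()]) or any
#'   data frame containing `age`, `pfmt`, `u_baseline`, `ui_type`, `arm`
#'   and the variables in `vars`.
#' @param vars character vector of analysis variables to diagnose;
#'   default: every numeric column with any missing value.
#' @param eligible optional named list mapping a variable to a logical
#'   vector of rows where that variable is scheduled to exist; rows
#'   outside it (e.g. the 4-week questionnaire of a patient who never
#'   had surgery) are structurally absent, not missing, and are
#'   excluded from the fraction and the model.
#' @return a `missingness_report`: data frame of per-variable fractions
#'   with a list-column of fitted models, and attributes
#'   `mi_triggered`.
#' @export
missingness_model <- function(data, vars = NULL, eligible = NULL) {
  if (is.null(vars)) {
    num <- names(data)[vapply(data, is.numeric, logical(1))]
    vars <- num[vapply(num, function(v) anyNA(data[[v]]), logical(1))]
  }
  covs <- c("age", "pfmt", "u_baseline", "ui_type", "arm")
  check_that(all(covs %in% names(data)), "data",
             sprintf("needs complete baseline covariates: %s",
                     paste(covs, collapse = ", ")))
  rows <- lapply(vars, function(v) {
    keep <- eligible[[v]] %||% rep(TRUE, nrow(data))
    miss <- as.integer(is.na(data[[v]][keep]))
    frac <- mean(miss)
    fit <- NULL; converged <- NA
    if (frac > 0 && frac < 1) {
      fit <- tryCatch(
        suppressWarnings(stats::glm(
          miss ~ age + pfmt + u_baseline + ui_type + arm,
          data = cbind(data[keep, covs, drop = FALSE], miss = miss),
          family = stats::binomial())),
        error = function(e) NULL)
      converged <- !is.null(fit) && isTRUE(fit$converged)
    }
    list(variable = v, fraction_missing = frac, converged = converged,
         fit = fit)
  })
  report <- data.frame(
    variable = vapply(rows, `[[`, character(1), "variable"),
    fraction_missing = vapply(rows, `[[`, numeric(1), "fraction_missing"),
    converged = vapply(rows, function(r) isTRUE(r$converged), logical(1)),
    stringsAsFactors = FALSE)
  report$fit <- lapply(rows, `[[`, "fit")
  attr(report, "mi_triggered") <- any(report$fraction_missing > 0.05)
  class(report) <- c("missingness_report", "data.frame")
  report
}

#' @export
print.missingness_report <- function(x, ...) {
  cat(sprintf("<missingness_report> %d variables, MI %s\n", nrow(x),
              if (isTRUE(attr(x, "mi_triggered"))) "triggered (>5% missing)"
              else "not triggered"))
  print(data.frame(variable = x$variable,
                   fraction_missing = round(x$fraction_missing, 3)))
  invisible(x)
}

#' Multiple imputation by predictive mean matching
#'
#' For each target variable with missing values: a linear regression on
#' the predictor set is fitted among observed cases; per imputation,
#' regression parameters are drawn from their approximate posterior
#' (proper imputation, so Rubin's-rules variances are valid); predictions
#' are formed for all cases (observed cases under the point estimate,
#' missing cases under the drawn parameters); each missing case copies
#' the observed outcome of one donor drawn uniformly from its `knn`
#' nearest observed cases by predicted value, equidistant donors all
#' entering the pool. Variables are processed in order of increasing
#' missingness and completed variables of the same group join the
#' predictor set of later ones, so information flows across time points.
#'
#' @param data data frame to impute.
#' @param targets named list of character vectors: groups of target
#'   variables (e.g. utilities, period costs). Variables without missing
#'   values pass through unchanged.
#' @param predictors character vector of complete baseline predictors.
#' @param m number of imputations (default 20).
#' @param knn donors per missing case (default 5).
#' @param seed integer seed.
#' @param proper logical; `FALSE` uses the point-estimate parameters in
#'   every imputation (deterministic-parameter PMM).
#' @return an `imputation_set`: list with `imputations` (list of m
#'   completed data frames), and the call parameters.
#' @export
impute_pmm <- function(data, targets, predictors, m = 20L, knn = 5L,
                       seed = 1L, proper = TRUE) {
  check_that(m >= 1, "m", "must be >= 1")
  check_that(knn >= 1, "knn", "must be >= 1")
  all_targets <- unlist(targets, use.names = FALSE)
  check_that(all(all_targets %in% names(data)), "targets",
             "all target variables must be columns of data")
  check_that(all(predictors %in% names(data)), "predictors",
             "all predictors must be columns of data")
  for (p in predictors)
    check_that(!anyNA(data[[p]]), p, "predictors must be complete")
  for (v in all_targets)
    check_that(is.numeric(data[[v]]), v, "imputation targets must be numeric")

  imputations <- with_seed(substream_seed(seed, "imputation"), {
    lapply(seq_len(m), function(im) {
      completed <- data
      for (g in seq_along(targets)) {
        grp <- targets[[g]]
        miss_frac <- vapply(grp, function(v) mean(is.na(data[[v]])),
                            numeric(1))
        done <- character(0)
        for (v in grp[order(miss_frac)]) {
          if (anyNA(completed[[v]])) {
            preds <- c(predictors, done)
            completed[[v]] <- pmm_one(completed, v, preds, knn, proper)
          }
          done <- c(done, v)
        }
      }
      completed
    })
  })
  structure(list(imputations = imputations, m = as.integer(m),
                 knn = as.integer(knn), seed = as.integer(seed),
                 proper = proper, targets = targets,
                 predictors = predictors),
            class = "imputation_set")
}

# Single-variable PMM draw. Returns the completed column.
pmm_one <- function(data, v, predictors, knn, proper) {
  obs <- !is.na(data[[v]])
  if (sum(obs) < knn)
    stop(sprintf("fewer complete cases (%d) than knn (%d) for %s",
                 sum(obs), knn, v))
  X <- stats::model.matrix(stats::as.formula(paste("~",
         paste(predictors, collapse = "+"))), data = data)
  y <- data[[v]]
  fit <- stats::lm.fit(X[obs, , drop = FALSE], y[obs])
  keep <- !is.na(fit$coefficients)   # drop aliased columns
  beta_hat <- fit$coefficients[keep]
  Xk <- X[, keep, drop = FALSE]
  n_obs <- sum(obs); p <- length(beta_hat)
  resid <- fit$residuals
  df <- max(n_obs - p, 1L)
  sigma2_hat <- sum(resid^2) / df
  if (proper) {
    sigma2_star <- sigma2_hat * df / stats::rchisq(1L, df)
    XtX <- crossprod(Xk[obs, , drop = FALSE])
    R <- chol(XtX + diag(1e-10, p))
    beta_star <- beta_hat +
      sqrt(sigma2_star) * backsolve(R, stats::rnorm(p))
  } else {
    beta_star <- beta_hat
  }
  yhat_obs <- as.vector(Xk[obs, , drop = FALSE] %*% beta_hat)
  yhat_mis <- as.vector(Xk[!obs, , drop = FALSE] %*% beta_star)
  y_obs <- y[obs]
  filled <- y
  mis_idx <- which(!obs)
  for (j in seq_along(mis_idx)) {
    d <- abs(yhat_obs - yhat_mis[j])
    kd <- sort(d, partial = min(knn, length(d)))[min(knn, length(d))]
    pool <- which(d <= kd + 1e-12)     # ties all enter the donor pool
    donor <- pool[sample.int(length(pool), 1L)]
    filled[mis_idx[j]] <- y_obs[donor]
  }
  filled
}

#' Pool estimates across imputations by Rubin's rules
#'
#' Pooled estimate is the mean of the per-imputation estimates; total
#' variance is the mean within-imputation variance plus `(1 + 1/m)`
#' times the between-imputation variance; degrees of freedom use the
#' standard small-sample formula and the confidence interval is from
#' the t distribution.
#'
#' @param estimates numeric vector of m per-imputation estimates.
#' @param variances numeric vector of m per-imputation variances.
#' @param conf confidence level (default 0.95).
#' @return list with `estimate`, `variance`, `se`, `df`, `ci`
#'   (length-2), `within`, `between`, `m`.
#' @export
rubins_pool <- function(estimates, variances, conf = 0.95) {
  check_that(length(estimates) == length(variances), "estimates",
             "estimates and variances must have equal length")
  m <- length(estimates)
  check_that(m >= 1, "estimates", "need at least one estimate")
  qbar <- mean(estimates)
  wbar <- mean(variances)
  if (m == 1L) {
    se <- sqrt(wbar)
    z <- stats::qnorm(1 - (1 - conf) / 2)
    return(list(estimate = qbar, variance = wbar, se = se, df = Inf,
                ci = qbar + c(-1, 1) * z * se, within = wbar, between = 0,
                m = 1L))
  }
  b <- stats::var(estimates)
  total <- wbar + (1 + 1 / m) * b
  df <- if (b > 0) (m - 1) * (1 + wbar / ((1 + 1 / m) * b))^2 else Inf
  se <- sqrt(total)
  tq <- stats::qt(1 - (1 - conf) / 2, df = df)
  list(estimate = qbar, variance = total, se = se, df = df,
       ci = qbar + c(-1, 1) * tq * se, within = wbar, between = b, m = m)
}
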