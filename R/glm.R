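# Covariate-adjusted GLMs for costs and QALYs: family/link selection by
# modified Park test, AIC and link diagnostics; cluster-robust sandwich
# covariance; incremental means by recycled predictions.

FAMILY_NAMES <- c("gaussian", "poisson", "Gamma", "inverse.gaussian")

make_family <- function(family, link) {
  check_that(family %in% FAMILY_NAMES, "family",
             sprintf("must be one of %s", paste(FAMILY_NAMES, collapse = ", ")))
  check_that(link %in% c("identity", "log"), "link",
             "must be identity or log")
  switch(family,
         gaussian = stats::gaussian(link = link),
         # Poisson-type: quasi-likelihood with variance proportional to
         # the mean, valid for continuous outcomes
         poisson = stats::quasipoisson(link = link),
         Gamma = stats::Gamma(link = link),
         inverse.gaussian = stats::inverse.gaussian(link = link))
}

#' Fit a covariate-adjusted GLM with cluster-robust covariance
#'
#' Fits `outcome ~ arm + covariates` by iteratively reweighted least
#' squares and attaches a sandwich covariance whose meat sums score
#' contributions within clusters (centres). Families requiring a
#' positive outcome (Gamma, inverse Gaussian) reject non-positive
#' values.
#'
#' @param data data frame containing the outcome, covariates and
#'   cluster variable; the `arm` column is coerced to a factor with the
#'   comparator as reference.
#' @param outcome name of the outcome column.
#' @param covariates character vector of adjustment covariates (the arm
#'   variable is always included first).
#' @param family one of `"gaussian"`, `"poisson"` (quasi-Poisson,
#'   variance proportional to the mean), `"Gamma"`,
#'   `"inverse.gaussian"`.
#' @param link `"identity"` or `"log"`.
#' @param cluster name of the cluster (centre) column.
#' @param arm_var name of the treatment indicator column.
#' @return a `glm_fit` object: the fitted `glm`, the cluster-robust
#'   covariance, and the model specification.
#' @export
fit_glm <- function(data, outcome, covariates = c("u_baseline", "pfmt", "age"),
                    family = "gaussian", link = "identity",
                    cluster = "centre", arm_var = "arm") {
  check_that(outcome %in% names(data), "outcome", "not a column of data")
  check_that(all(c(covariates, cluster, arm_var) %in% names(data)),
             "covariates", "all covariates and the cluster must be columns")
  y <- data[[outcome]]
  check_that(!anyNA(y), outcome,
             "outcome contains missing values; impute or drop first")
  if (family %in% c("Gamma", "inverse.gaussian"))
    check_that(all(y > 0), outcome,
               sprintf("%s family requires a strictly positive outcome",
                       family))
  df <- data
  if (!is.factor(df[[arm_var]]))
    df[[arm_var]] <- factor(df[[arm_var]],
                            levels = c("comparator", "intervention"))
  form <- stats::reformulate(c(arm_var, covariates), response = outcome)
  fam <- make_family(family, link)
  fit <- if (link == "log" && family == "gaussian" && any(y <= 0)) {
    # log-link needs positive starting means even when the Gaussian
    # outcome has non-positive values
    eps <- max(1e-8, 0.01 * mean(abs(y)))
    stats::glm(form, data = df, family = fam, mustart = pmax(y, eps))
  } else if (family == "inverse.gaussian") {
    # the inverse-Gaussian IRLS is fragile from its default start; seed
    # it with Gamma coefficients under the same link
    start <- tryCatch(
      stats::coef(stats::glm(form, data = df,
                             family = stats::Gamma(link = link))),
      error = function(e) NULL)
    stats::glm(form, data = df, family = fam, start = start)
  } else {
    stats::glm(form, data = df, family = fam)
  }
  if (!fit$converged)
    stop(sprintf("GLM (%s, %s) did not converge in %d IRLS iterations",
                 family, link, fit$iter))
  qr_rank <- fit$qr$rank
  if (qr_rank < length(stats::coef(fit)))
    stop("singular design: some coefficients are not estimable")
  structure(list(
    fit = fit,
    vcov_cluster = cluster_vcov(fit, df[[cluster]]),
    spec = list(outcome = outcome, covariates = covariates,
                family = family, link = link, cluster = cluster,
                arm_var = arm_var),
    data = df
  ), class = "glm_fit")
}

# Sandwich covariance with scores summed within clusters and a
# G/(G-1) small-sample correction.
cluster_vcov <- function(fit, cluster_ids) {
  X <- stats::model.matrix(fit)
  mu <- fit$fitted.values
  eta <- fit$linear.predictors
  fam <- fit$family
  y <- fit$y
  u <- (y - mu) * fam$mu.eta(eta) / fam$variance(mu)
  scores <- X * u
  g <- as.factor(cluster_ids)
  G <- nlevels(g)
  sg <- rowsum(scores, g)
  meat <- crossprod(sg) * G / max(G - 1, 1)
  bread <- summary(fit)$cov.unscaled
  v <- bread %*% meat %*% bread
  (v + t(v)) / 2
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("<glm_fit> %s ~ %s + ... | family %s, link %s, clustered by %s\n",
              x$spec$outcome, x$spec$arm_var, x$spec$family, x$spec$link,
              x$spec$cluster))
  co <- stats::coef(x$fit)
  se <- sqrt(diag(x$vcov_cluster))
  print(round(cbind(estimate = co, cluster_se = se), 4))
  invisible(x)
}

#' Modified Park test for the variance-to-mean power law
#'
#' Regresses the squared raw residuals of a fitted model on the log of
#' the fitted mean in a Gamma-family, log-link GLM; the slope `lambda`
#' indexes variance proportional to `mean^lambda`, and the nearest
#' integer recommends the family: 0 Gaussian, 1 Poisson-type, 2 Gamma,
#' 3 inverse Gaussian.
#'
#' @param fitres a `glm_fit` (fitted means must be strictly positive).
#' @return list with `lambda`, `recommended` family name, and the park
#'   regression fit.
#' @export
modified_park_test <- function(fitres) {
  stopifnot(inherits(fitres, "glm_fit"))
  mu <- fitres$fit$fitted.values
  check_that(all(mu > 0), "fitted values",
             "Park test requires strictly positive fitted values")
  res2 <- (fitres$fit$y - mu)^2
  keep <- res2 > 0
  pf <- suppressWarnings(stats::glm(res2[keep] ~ log(mu[keep]),
                                    family = stats::Gamma(link = "log")))
  lambda <- unname(stats::coef(pf)[2])
  idx <- min(max(round(lambda), 0), 3)
  list(lambda = lambda, recommended = FAMILY_NAMES[idx + 1L], park_fit = pf)
}

#' Link diagnostics for a fitted GLM
#'
#' Three goodness-of-link checks: the Pregibon link test (refit with the
#' squared linear predictor added; its coefficient's p-value), a
#' modified Hosmer-Lemeshow test (F-test that mean raw-scale residuals
#' are zero across deciles of the fitted values), and the Pearson
#' correlation test between raw-scale residuals and fitted values.
#' Small p-values indicate link misspecification.
#'
#' @param fitres a `glm_fit`.
#' @param groups number of fitted-value groups for the
#'   Hosmer-Lemeshow test (default 10; reduced with a warning when
#'   there are fewer distinct fitted values).
#' @return named numeric `c(pregibon=, hosmer_lemeshow=, pearson=)` of
#'   p-values.
#' @export
link_diagnostics <- function(fitres, groups = 10L) {
  stopifnot(inherits(fitres, "glm_fit"))
  fit <- fitres$fit
  y <- fit$y
  eta <- fit$linear.predictors
  mu <- fit$fitted.values
  fam <- fit$family

  preg <- tryCatch({
    pf <- suppressWarnings(stats::glm(y ~ eta + I(eta^2), family = fam))
    stats::coef(summary(pf))["I(eta^2)", 4]
  }, error = function(e) NA_real_)

  r <- y - mu
  n_distinct <- length(unique(mu))
  g_use <- min(groups, n_distinct)
  if (g_use < groups)
    warning(sprintf("only %d distinct fitted values; using %d HL groups",
                    n_distinct, g_use))
  grp <- cut(rank(mu, ties.method = "first"),
             breaks = g_use, labels = FALSE)
  f0 <- stats::lm(r ~ 0)
  f1 <- stats::lm(r ~ 0 + factor(grp))
  hl <- stats::anova(f0, f1)[2, "Pr(>F)"]

  pear <- stats::cor.test(r, mu)$p.value

  c(pregibon = unname(preg), hosmer_lemeshow = unname(hl),
    pearson = unname(pear))
}

#' Select a GLM family and link for an outcome
#'
#' Fits every candidate family/link pair, recommends a family from the
#' modified Park test on a reference log-link fit, cross-checks against
#' minimum AIC (where defined), and chooses the link whose diagnostics
#' pass for the chosen family. The Park recommendation wins over AIC
#' when the two disagree; the disagreement is recorded in the decision
#' table.
#'
#' @param data,outcome,covariates,cluster,arm_var as in [fit_glm()].
#' @param candidates data frame with columns `family`, `link`; default
#'   grid covers Gaussian identity/log and Poisson-type, Gamma and
#'   inverse Gaussian with log link.
#' @return list with the chosen `family`, `link`, per-candidate
#'   `decision_table`, the Park `lambda`, and the chosen `fit`.
#' @export
select_family_link <- function(data, outcome,
                               covariates = c("u_baseline", "pfmt", "age"),
                               cluster = "centre", arm_var = "arm",
                               candidates = default_candidates()) {
  check_that(nrow(candidates) >= 1, "candidates", "need at least one")
  if (nrow(candidates) == 1L) {
    fitted <- fit_glm(data, outcome, covariates, candidates$family[1],
                      candidates$link[1], cluster, arm_var)
    return(list(family = candidates$family[1], link = candidates$link[1],
                decision_table = candidates, lambda = NA_real_,
                fit = fitted))
  }
  fits <- vector("list", nrow(candidates))
  tab <- candidates
  tab$fitted <- FALSE
  tab$aic <- NA_real_
  tab$pregibon <- tab$hosmer_lemeshow <- tab$pearson <- NA_real_
  for (i in seq_len(nrow(candidates))) {
    fits[[i]] <- tryCatch(
      fit_glm(data, outcome, covariates, candidates$family[i],
              candidates$link[i], cluster, arm_var),
      error = function(e) NULL)
    if (!is.null(fits[[i]])) {
      tab$fitted[i] <- TRUE
      tab$aic[i] <- suppressWarnings(stats::AIC(fits[[i]]$fit))
      d <- tryCatch(suppressWarnings(link_diagnostics(fits[[i]])),
                    error = function(e) c(NA_real_, NA_real_, NA_real_))
      tab$pregibon[i] <- d[1]; tab$hosmer_lemeshow[i] <- d[2]
      tab$pearson[i] <- d[3]
    }
  }
  # Park lambda from a positive-mean reference fit (first fitted
  # log-link candidate, else any fit with positive fitted values)
  ref <- NULL
  for (i in order(candidates$link != "log")) {
    f <- fits[[i]]
    if (!is.null(f) && all(f$fit$fitted.values > 0)) { ref <- f; break }
  }
  lambda <- NA_real_
  park_family <- NA_character_
  if (!is.null(ref)) {
    pk <- tryCatch(modified_park_test(ref), error = function(e) NULL)
    if (!is.null(pk)) { lambda <- pk$lambda; park_family <- pk$recommended }
  }
  aic_family <- if (any(!is.na(tab$aic)))
    tab$family[which.min(tab$aic)] else NA_character_
  family <- if (!is.na(park_family) &&
                park_family %in% tab$family[tab$fitted]) park_family
            else if (!is.na(aic_family)) aic_family
            else tab$family[tab$fitted][1]
  agree <- identical(park_family, aic_family)
  # link: among fitted candidates of the chosen family, most diagnostics
  # passed at 5%; ties broken by candidate order
  rows <- which(tab$family == family & tab$fitted)
  if (length(rows) == 0L) rows <- which(tab$fitted)
  if (length(rows) == 0L)
    stop("no candidate family/link could be fitted to the outcome")
  score <- vapply(rows, function(i)
    sum(c(tab$pregibon[i], tab$hosmer_lemeshow[i], tab$pearson[i]) > 0.05,
        na.rm = TRUE), numeric(1))
  pick <- rows[which.max(score)]
  attr(tab, "park") <- c(lambda = lambda, family = park_family)
  attr(tab, "aic_family") <- aic_family
  attr(tab, "park_aic_agree") <- agree
  list(family = tab$family[pick], link = tab$link[pick],
       decision_table = tab, lambda = lambda, fit = fits[[pick]])
}

#' @rdname select_family_link
#' @export
default_candidates <- function() {
  data.frame(
    family = c("gaussian", "gaussian", "poisson", "Gamma",
               "inverse.gaussian"),
    link = c("identity", "log", "log", "log", "log"),
    stringsAsFactors = FALSE)
}

#' Adjusted incremental mean by recycled predictions
#'
#' Predicts every patient's outcome under each arm and differences the
#' two prediction means. For the identity link this equals the arm
#' coefficient exactly and the confidence interval uses the
#' cluster-robust variance with `G - 1` degrees of freedom; for other
#' links the default CI resamples centres non-parametrically
#' (`method = "bootstrap"`), with a delta-method alternative.
#'
#' @param fitres a `glm_fit`.
#' @param method `"auto"` (identity link: closed form; otherwise
#'   bootstrap), `"delta"`, `"bootstrap"`, or `"none"` (point estimate
#'   only).
#' @param B bootstrap replicates (default 500).
#' @param seed seed for the bootstrap.
#' @param conf confidence level.
#' @return list with `estimate`, `se`, `ci`, `method`.
#' @export
adjusted_mean_difference <- function(fitres, method = "auto", B = 500L,
                                     seed = 1L, conf = 0.95) {
  stopifnot(inherits(fitres, "glm_fit"))
  est <- recycled_difference(fitres)
  if (method == "none")
    return(list(estimate = est, se = NA_real_, ci = c(NA_real_, NA_real_),
                method = "none"))
  if (method == "auto")
    method <- if (fitres$spec$link == "identity") "delta" else "bootstrap"
  G <- length(unique(fitres$data[[fitres$spec$cluster]]))
  alpha <- 1 - conf
  if (method == "delta") {
    v <- delta_variance(fitres)
    se <- sqrt(v)
    tq <- stats::qt(1 - alpha / 2, df = max(G - 1, 1))
    ci <- est + c(-1, 1) * tq * se
  } else {
    draws <- with_seed(substream_seed(seed, "amd-bootstrap"), {
      cl <- fitres$data[[fitres$spec$cluster]]
      centres <- unique(cl)
      vapply(seq_len(B), function(b) {
        pick <- sample(centres, length(centres), replace = TRUE)
        dfb <- do.call(rbind, lapply(seq_along(pick), function(j) {
          d <- fitres$data[cl == pick[j], , drop = FALSE]
          d[[fitres$spec$cluster]] <- paste0("bs", j)
          d
        }))
        out <- tryCatch({
          f <- fit_glm(dfb, fitres$spec$outcome, fitres$spec$covariates,
                       fitres$spec$family, fitres$spec$link,
                       fitres$spec$cluster, fitres$spec$arm_var)
          recycled_difference(f)
        }, error = function(e) NA_real_)
        out
      }, numeric(1))
    })
    draws <- draws[!is.na(draws)]
    se <- stats::sd(draws)
    ci <- unname(stats::quantile(draws, c(alpha / 2, 1 - alpha / 2)))
  }
  list(estimate = est, se = se, ci = ci, method = method)
}

recycled_difference <- function(fitres) {
  spec <- fitres$spec
  d1 <- fitres$data; d1[[spec$arm_var]] <- factor("intervention",
    levels = levels(fitres$data[[spec$arm_var]]))
  d0 <- fitres$data; d0[[spec$arm_var]] <- factor("comparator",
    levels = levels(fitres$data[[spec$arm_var]]))
  mean(stats::predict(fitres$fit, newdata = d1, type = "response")) -
    mean(stats::predict(fitres$fit, newdata = d0, type = "response"))
}

# Delta-method variance of the recycled-prediction difference using the
# cluster-robust coefficient covariance.
delta_variance <- function(fitres) {
  spec <- fitres$spec
  fam <- fitres$fit$family
  tt <- stats::terms(fitres$fit)
  grad_for <- function(level) {
    d <- fitres$data
    d[[spec$arm_var]] <- factor(level,
                                levels = levels(fitres$data[[spec$arm_var]]))
    mf <- stats::model.frame(stats::delete.response(tt), d,
                             xlev = fitres$fit$xlevels)
    X <- stats::model.matrix(stats::delete.response(tt), mf,
                             contrasts.arg = fitres$fit$contrasts)
    eta <- as.vector(X %*% stats::coef(fitres$fit))
    colMeans(X * fam$mu.eta(eta))
  }
  g <- grad_for("intervention") - grad_for("comparator")
  as.numeric(t(g) %*% fitres$vcov_cluster %*% g)
}

#' Per-arm adjusted mean outcome (recycled predictions)
#'
#' @param fitres a `glm_fit`.
#' @return named numeric `c(intervention=, comparator=)`.
#' @export
adjusted_arm_means <- function(fitres) {
  spec <- fitres$spec
  out <- vapply(c("intervention", "comparator"), function(a) {
    d <- fitres$data
    d[[spec$arm_var]] <- factor(a, levels = levels(fitres$data[[spec$arm_var]]))
    mean(stats::predict(fitres$fit, newdata = d, type = "response"))
  }, numeric(1))
  out
}
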