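test_that("Gaussian/identity equals OLS; singleton clusters give the HC form", {
  d <- glm_frame(120, seed = 81)
  d$centre <- seq_len(nrow(d))  # one observation per cluster
  set.seed(81)
  d$y <- 2 + 0.5 * (d$arm == "intervention") + 0.3 * d$u_baseline + rnorm(120)
  f <- fit_glm(d, "y", c("u_baseline", "pfmt", "age"))
  ols <- lm(y ~ factor(arm, c("comparator", "intervention")) + u_baseline +
              pfmt + age, data = d)
  expect_equal(unname(coef(f$fit)), unname(coef(ols)), tolerance = 1e-12)
  # independent HC computation: bread (X'X)^-1, meat sum x x' e^2, with
  # the G/(G-1) correction
  X <- model.matrix(ols)
  e <- resid(ols)
  bread <- solve(crossprod(X))
  meat <- crossprod(X * e) * nrow(d) / (nrow(d) - 1)
  expect_equal(unname(f$vcov_cluster), unname(bread %*% meat %*% bread),
               tolerance = 1e-10)
})

test_that("duplicating every cluster leaves coefficients unchanged", {
  d <- glm_frame(150, seed = 82)
  set.seed(82)
  d$y <- exp(0.5 + 0.2 * (d$arm == "intervention") +
               0.3 * d$u_baseline) * rgamma(150, 5, 5)
  f1 <- fit_glm(d, "y", "u_baseline", family = "Gamma", link = "log")
  d2 <- rbind(d, transform(d, centre = centre + 100))
  f2 <- fit_glm(d2, "y", "u_baseline", family = "Gamma", link = "log")
  expect_equal(coef(f1$fit), coef(f2$fit), tolerance = 1e-6)
})

test_that("Gamma/log coefficients recovered on simulated data", {
  set.seed(83)
  n <- 5000
  d <- glm_frame(n, seed = 83)
  eta <- 1 + 0.4 * (d$arm == "intervention") + 0.8 * d$u_baseline
  d$y <- rgamma(n, shape = 4, scale = exp(eta) / 4)
  f <- fit_glm(d, "y", "u_baseline", family = "Gamma", link = "log")
  se <- sqrt(diag(f$vcov_cluster))
  co <- coef(f$fit)
  expect_lt(abs(co[["armintervention"]] - 0.4), 2 * se[2])
  expect_lt(abs(co[["u_baseline"]] - 0.8), 2 * se[3])
  # positivity precondition enforced
  d$y[1] <- 0
  expect_error(fit_glm(d, "y", "u_baseline", family = "Gamma", link = "log"),
               class = "trialcea_validation_error")
})

test_that("modified Park test indexes the variance power law", {
  set.seed(84)
  n <- 4000
  d <- glm_frame(n, seed = 84)
  mu <- exp(1 + 1.2 * d$u_baseline)
  mk <- function(lam) {
    d$y <- mu + rnorm(n, 0, 0.4 * mu^(lam / 2))
    fit_glm(d, "y", "u_baseline", family = "gaussian", link = "log")
  }
  pk0 <- modified_park_test(mk(0))
  expect_lt(abs(pk0$lambda - 0), 0.3)
  expect_equal(pk0$recommended, "gaussian")
  pk2 <- modified_park_test(mk(2))
  expect_lt(abs(pk2$lambda - 2), 0.3)
  expect_equal(pk2$recommended, "Gamma")
  pk3 <- modified_park_test(mk(3))
  expect_lt(abs(pk3$lambda - 3), 0.3)
  expect_equal(pk3$recommended, "inverse.gaussian")
  # nonpositive fitted values are rejected
  d$y <- rnorm(n)
  f_id <- fit_glm(d, "y", "u_baseline")
  expect_error(modified_park_test(f_id), class = "trialcea_validation_error")
})

test_that("link diagnostics flag a grossly wrong link and pass a right one", {
  set.seed(85)
  n <- 2000
  d <- glm_frame(n, seed = 85)
  d$y <- exp(1 + 2 * d$u_baseline) + rnorm(n, 0, 0.5)
  wrong <- fit_glm(d, "y", "u_baseline", family = "gaussian",
                   link = "identity")
  dw <- link_diagnostics(wrong)
  expect_lt(dw[["pregibon"]], 0.05)
  right <- fit_glm(d, "y", "u_baseline", family = "gaussian", link = "log")
  dr <- link_diagnostics(right)
  expect_gt(dr[["pregibon"]], 0.05)
  # OLS residuals are orthogonal to fitted values by construction
  set.seed(86)
  d$y <- 1 + d$u_baseline + rnorm(n)
  ols_fit <- fit_glm(d, "y", "u_baseline")
  expect_lt(abs(cor(ols_fit$fit$y - fitted(ols_fit$fit),
                    fitted(ols_fit$fit))), 1e-10)
  expect_gt(link_diagnostics(ols_fit)[["pearson"]], 0.99)
})

test_that("family/link selection reproduces the expected choices", {
  set.seed(87)
  n <- 4000
  d <- glm_frame(n, seed = 87)
  # cost-like: multiplicative covariates, variance ~ mean^3 (gamma with
  # shape inversely proportional to the mean keeps the outcome positive)
  mu <- exp(6 + 0.5 * d$u_baseline + 0.1 * (d$arm == "intervention"))
  d$y <- rgamma(n, shape = 500 / mu, scale = mu^2 / 500)
  sel <- select_family_link(d, "y", covariates = "u_baseline")
  expect_equal(sel$family, "inverse.gaussian")
  expect_equal(sel$link, "log")
  expect_true(is.data.frame(sel$decision_table))
  # homoscedastic additive data: Gaussian identity
  d$y <- 5 + 2 * d$u_baseline + rnorm(n)
  sel2 <- select_family_link(d, "y", covariates = "u_baseline")
  expect_equal(sel2$family, "gaussian")
  expect_equal(sel2$link, "identity")
  # single candidate passes through
  sel3 <- select_family_link(d, "y", covariates = "u_baseline",
                             candidates = data.frame(family = "gaussian",
                                                     link = "identity"))
  expect_equal(sel3$family, "gaussian")
})

test_that("recycled-prediction differences: identity exactness, log-link oracle", {
  d <- glm_frame(200, seed = 88)
  set.seed(88)
  d$y <- 1 + 0.7 * (d$arm == "intervention") + 0.2 * d$u_baseline + rnorm(200)
  f <- fit_glm(d, "y", c("u_baseline", "pfmt", "age"))
  amd <- adjusted_mean_difference(f)
  expect_equal(amd$estimate, unname(coef(f$fit)["armintervention"]),
               tolerance = 1e-12)
  expect_true(amd$ci[1] < amd$estimate && amd$estimate < amd$ci[2])

  # four-patient log-link fit: hand-compute the prediction means from
  # the coefficient vector and design matrices
  d4 <- data.frame(arm = c("intervention", "intervention", "comparator",
                           "comparator"),
                   u_baseline = c(0.6, 0.9, 0.7, 0.8),
                   centre = c(1, 1, 2, 2),
                   y = c(3.2, 5.1, 2.4, 2.9))
  f4 <- fit_glm(d4, "y", "u_baseline", family = "gaussian", link = "log")
  b <- coef(f4$fit)
  by_hand <- mean(exp(b[1] + b[2] + b[3] * d4$u_baseline)) -
    mean(exp(b[1] + b[3] * d4$u_baseline))
  amd4 <- adjusted_mean_difference(f4, method = "none")
  expect_equal(amd4$estimate, by_hand, tolerance = 1e-10)

  # bootstrap CI method runs and brackets the point estimate
  amd_b <- adjusted_mean_difference(f, method = "bootstrap", B = 60, seed = 4)
  expect_true(amd_b$ci[1] <= amd$estimate && amd$estimate <= amd_b$ci[2])
})

test_that("singular designs and missing outcomes are rejected", {
  d <- glm_frame(50, seed = 89)
  d$y <- rnorm(50)
  d$dup <- d$u_baseline
  expect_error(fit_glm(d, "y", c("u_baseline", "dup")), "singular")
  d$y[1] <- NA
  expect_error(fit_glm(d, "y", "u_baseline"),
               class = "trialcea_validation_error")
})
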