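test_that("net monetary benefit arithmetic and linearity", {
  # the base-case incremental pair: saving 6 and gaining 0.005 QALYs is
  # worth 20000 * 0.005 + 6 at the standard threshold
  expect_equal(nmb(-6, 0.005, 20000), 106)
  expect_equal(nmb(-6, 0.005, 0), 6)
  lams <- c(0, 10000, 20000, 40000)
  vals <- nmb(150, 0.01, lams)
  expect_equal(diff(vals) / diff(lams), rep(0.01, 3))
  expect_error(nmb(0, 0, -5), class = "trialcea_validation_error")
})

test_that("ICER quadrants and dominance labels", {
  # cheaper and more effective: comparator dominated, no ratio
  r1 <- icer(-6, 0.005)
  expect_equal(r1$label, "comparator dominated")
  expect_equal(r1$quadrant, "SE")
  expect_true(is.na(r1$value))
  # southwest: cost saving per QALY lost, positive ratio
  r2 <- icer(-209, -0.096)
  expect_equal(r2$quadrant, "SW")
  expect_equal(r2$value, -209 / -0.096)
  expect_match(r2$label, "cost saving per QALY lost")
  # costlier, less effective
  r3 <- icer(100, -0.01)
  expect_equal(r3$label, "intervention dominated")
  # northeast ratio; zero cost difference gives a zero ICER
  expect_equal(icer(0, 1)$value, 0)
  expect_equal(icer(500, 0.05)$value, 10000)
  # zero QALY difference: undefined ratio
  r0 <- icer(50, 0)
  expect_true(is.na(r0$value))
  expect_match(r0$label, "undefined")
})

test_that("CEAC limits, complement identity and bounds", {
  set.seed(91)
  draws <- data.frame(delta_cost = rnorm(400, 20, 150),
                      delta_qaly = rnorm(400, 0.01, 0.05))
  grid <- c(0, 500, 20000, 30000, 1e7)
  cc <- ceac(draws, grid)
  expect_true(all(cc$p_intervention >= 0 & cc$p_intervention <= 1))
  expect_equal(cc$p_intervention + cc$p_comparator, rep(1, length(grid)))
  # lambda = 0: probability the intervention is cheaper
  expect_equal(cc$p_intervention[1], mean(draws$delta_cost < 0))
  # lambda -> infinity: probability the intervention is more effective
  expect_equal(cc$p_intervention[length(grid)],
               mean(draws$delta_qaly > 0), tolerance = 0.01)
  # all draws northwest of the origin: certainty at every lambda
  nw <- data.frame(delta_cost = -abs(rnorm(50)) - 1,
                   delta_qaly = abs(rnorm(50)) + 0.01)
  expect_equal(ceac(nw, grid)$p_intervention, rep(1, length(grid)))
  expect_error(ceac(draws, numeric(0)), class = "trialcea_validation_error")
})

test_that("bootstrap draws: degenerate identity and consistency", {
  ds <- generate_trial(null_config(n_per_arm = 60L, seed = 95,
                                   target_missing_fraction = 0,
                                   n_centres = 1L))
  tab <- derive_outcomes(build_analysis_table(ds))
  # a single centre makes centre-resampling the identity permutation:
  # every draw equals the point estimate
  point <- incremental_estimator(tab)
  dr <- bootstrap_cea(list(tab), B = 3, seed = 1)
  expect_equal(dr$delta_cost, rep(unname(point["delta_cost"]), 3))
  expect_equal(dr$delta_qaly, rep(unname(point["delta_qaly"]), 3))
  expect_identical(dr$imputation, rep(1L, 3))
  # same seed, same draws
  dr2 <- bootstrap_cea(list(tab), B = 3, seed = 1)
  expect_equal(as.data.frame(dr), as.data.frame(dr2))
})

test_that("bootstrap cloud centres on the point estimate under the null", {
  ds <- generate_trial(null_config(n_per_arm = 120L, seed = 96,
                                   target_missing_fraction = 0))
  tab <- derive_outcomes(build_analysis_table(ds))
  point <- incremental_estimator(tab)
  dr <- bootstrap_cea(list(tab), B = 300, seed = 2)
  se_c <- sd(dr$delta_cost) / sqrt(nrow(dr))
  expect_lt(abs(mean(dr$delta_cost) - point["delta_cost"]), 3 * se_c)
  se_q <- sd(dr$delta_qaly) / sqrt(nrow(dr))
  expect_lt(abs(mean(dr$delta_qaly) - point["delta_qaly"]), 3 * se_q)
  # null world: the cloud spans all four quadrants
  q <- quadrant_fracs <- table(paste0(dr$delta_cost >= 0, dr$delta_qaly > 0))
  expect_equal(length(q), 4L)
})

test_that("estimator failures are dropped, and excess failure aborts", {
  ds <- generate_trial(null_config(n_per_arm = 30L, seed = 97,
                                   target_missing_fraction = 0))
  tab <- derive_outcomes(build_analysis_table(ds))
  flaky_calls <- 0
  always_fail <- function(t) stop("boom")
  expect_error(bootstrap_cea(list(tab), B = 20, seed = 3,
                             estimator = always_fail), "aborted")
})
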