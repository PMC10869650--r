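test_that("tariff valuation matches hand-summed coefficients", {
  # full health is exactly 1 under any admissible tariff
  expect_identical(value_eq5d(c(1, 1, 1, 1, 1)), 1)
  # worst state: 1 - (constants + all level-3 decrements), summed by hand
  # from the shipped coefficient file
  tabfile <- system.file("extdata", "eq5d_tariff_uk.csv",
                         package = "trialcea")
  raw <- read.csv(tabfile)
  worst_sum <- sum(raw$decrement[is.na(raw$level) | raw$level == 3])
  expect_equal(value_eq5d(c(3, 3, 3, 3, 3)), 1 - worst_sum)
  expect_equal(value_eq5d(c(3, 3, 3, 3, 3)), -0.594)
  # two-term arithmetic: any-dysfunction constant + mobility level 2
  expect_equal(value_eq5d(c(2, 1, 1, 1, 1)), 1 - 0.081 - 0.069)
  # out-of-range levels rejected; missing marked NA
  expect_error(value_eq5d(c(0, 1, 1, 1, 1)),
               class = "trialcea_validation_error")
  expect_error(value_eq5d(c(1, 1, 4, 1, 1)),
               class = "trialcea_validation_error")
  expect_true(is.na(value_eq5d(c(1, NA, 1, 1, 1))))
})

test_that("valuation is monotone non-increasing over all 243 states", {
  states <- eq5d_states()
  vals <- value_eq5d(states)
  for (j in 1:5) {
    can_worsen <- states[, j] < 3
    worse <- states[can_worsen, , drop = FALSE]
    worse[, j] <- worse[, j] + 1L
    expect_true(all(value_eq5d(worse) <= vals[can_worsen]))
  }
  # the shipped table round-trips through CSV
  path <- withr::local_tempfile(fileext = ".csv")
  write_tariff(eq5d_tariff_uk(), path)
  again <- read_tariff(path)
  expect_equal(value_eq5d(states, again), vals)
})

test_that("condition-specific mapping obeys its additive contract", {
  # toy mapping with two items, decrements 0.01 / 0.02 at the worst level
  toy <- utility_tariff(
    any_dysfunction = 0, worst_level = 0,
    decrements = data.frame(dimension = c("a", "a", "b", "b"),
                            level = c(2L, 3L, 2L, 3L),
                            decrement = c(0.005, 0.01, 0.01, 0.02)),
    max_level = 3L)
  expect_equal(value_iciq(c(3, 3), toy), 1 - 0.03)
  expect_equal(value_iciq(c(1, 1), toy), 1)       # best pattern -> maximum
  r <- c(2, 3)
  expect_identical(value_iciq(r, toy), value_iciq(r, toy))  # deterministic
  # missing item -> missing utility, not an error
  expect_true(is.na(value_iciq(c(NA, 2), toy)))
  # default synthetic mapping stays in a plausible narrow band
  m <- iciq_mapping_synthetic()
  expect_equal(value_iciq(rep(1, 8), m), 1)
  expect_gt(value_iciq(rep(4, 8), m), 0.5)
})

test_that("QALY closed forms: rectangle and annual-bucket discounting", {
  tr <- utility_trajectory(c(0, 1095.75), c(1, 1))
  expect_equal(qaly_auc(tr, qaly_options(discount_rate = 0)), 3,
               tolerance = 1e-12)
  q <- qaly_auc(tr, qaly_options(discount_rate = 0.035))
  expect_equal(q, 1 + 1 / 1.035 + 1 / 1.035^2, tolerance = 1e-12)
  expect_equal(round(q, 4), 2.8997)
})

test_that("qaly_auc equals the fine-grid numerical oracle", {
  set.seed(404)
  for (i in 1:200) {
    k <- sample(3:7, 1)
    tt <- sort(c(0, runif(k - 2, 1, 1095), runif(1, 1095.75, 1200)))
    uu <- runif(k, -0.2, 1)
    r <- runif(1, 0, 0.06)
    tr <- utility_trajectory(tt, uu)
    expect_equal(qaly_auc(tr, qaly_options(discount_rate = r)),
                 auc_grid_oracle(tt, uu, r), tolerance = 1e-9)
  }
})

test_that("qaly_auc properties: monotone, discount decreases, wait adjustment", {
  tt <- c(0, 120, 456, 730, 1096)
  uu <- c(0.7, 0.9, 0.8, 0.85, 0.8)
  tr <- utility_trajectory(tt, uu)
  base <- qaly_auc(tr, qaly_options(discount_rate = 0))
  # raising any single utility never decreases the QALY
  for (j in seq_along(uu)) {
    up <- uu; up[j] <- min(up[j] + 0.1, 1)
    expect_gte(qaly_auc(utility_trajectory(tt, up),
                        qaly_options(discount_rate = 0)), base)
  }
  # discounting strictly decreases any trajectory positive after month 12
  expect_lt(qaly_auc(tr, qaly_options(discount_rate = 0.035)), base)
  # with the adjustment off the result is the plain discounted trapezoid
  tr_s <- utility_trajectory(tt, uu, surgery_day = 60)
  off <- qaly_auc(tr_s, qaly_options(discount_rate = 0.02,
                                     adjust_surgery_wait = FALSE))
  expect_equal(off, auc_grid_oracle(tt, uu, 0.02), tolerance = 1e-9)
  # with it on, utility is flat at baseline until surgery: equivalent to
  # integrating the modified knot set
  on <- qaly_auc(tr_s, qaly_options(discount_rate = 0.02))
  t_adj <- c(0, 60, tt[-1])
  u_adj <- c(0.7, 0.7, uu[-1])
  expect_equal(on, auc_grid_oracle(t_adj, u_adj, 0.02), tolerance = 1e-9)
  expect_lt(on, off)  # waiting at the lower baseline loses QALYs here
})

test_that("qaly_auc degenerate inputs", {
  expect_error(qaly_auc(utility_trajectory(c(0, 456), c(NA, NA))),
               "impute")
  # not extrapolated past the last observation: left missing
  expect_true(is.na(qaly_auc(utility_trajectory(c(0, 456, 730),
                                                c(0.8, 0.8, 0.8)))))
  expect_error(utility_trajectory(c(0, 0), c(1, 1)),
               class = "trialcea_validation_error")
  expect_error(utility_trajectory(c(0, 10), c(1, 1.2)),
               class = "trialcea_validation_error")
})
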