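test_that("intervention micro-costing sums its components", {
  uc <- toy_unit_costs()
  # 30 min theatre at a staff-inclusive 10/min plus a 100 device
  rec <- toy_intervention_record(theatre_minutes = 30)
  expect_equal(cost_intervention(rec, uc), 400)
  # empty component sum is zero
  empty <- toy_intervention_record(theatre_minutes = 0, device_type = NA,
                                   device_count = 0L, anaesthesia = NA)
  expect_equal(cost_intervention(empty, uc), 0)
  # deterministic
  expect_identical(cost_intervention(rec, uc), cost_intervention(rec, uc))
  # every priced component enters: anaesthetist, nurses, drugs, recovery,
  # stay, catheters, return to theatre, consumables
  uc2 <- toy_unit_costs(list(anaesthetist_per_min = 2,
                             nurse_band5_per_min = 1,
                             nurse_band4_per_min = 0.5,
                             theatre_per_min = 5, anaesthesia_general = 30,
                             recovery_per_min = 1, ward_day = 250,
                             catheter = 5, return_to_theatre = 500))
  rec2 <- toy_intervention_record(theatre_minutes = 10,
                                  anaesthesia = "general",
                                  anaesthetist_present = TRUE,
                                  recovery_minutes = 20, los_days = 1L,
                                  catheters = 2L, return_theatre = TRUE,
                                  consumables_cost = 12.5)
  # 10*(10 + 2 + 2*1 + 1*0.5 + 5) + 100 + 30 + 20 + 250 + 10 + 500 + 12.5
  expect_equal(cost_intervention(rec2, uc2),
               10 * 19.5 + 100 + 30 + 20 + 250 + 10 + 500 + 12.5)
  # unknown device code is named in the error
  bad <- toy_intervention_record(device_type = "laser")
  expect_error(cost_intervention(bad, uc), "device_laser")
})

test_that("follow-up costing distinguishes zero answers from missing", {
  uc <- toy_unit_costs()
  counts <- data.frame(item = c("gp_visit", "outpatient_visit"),
                       count = c(2L, 1L))
  expect_equal(cost_followup(counts, uc, "15m"),
               c(primary = 60, secondary = 120))
  # all-"no" answers cost zero in both sectors
  zero <- data.frame(item = c("gp_visit", "nurse_visit", "outpatient_visit",
                              "inpatient_day"), count = 0L)
  expect_equal(cost_followup(zero, uc, "3m"), c(primary = 0, secondary = 0))
  # an unanswered questionnaire stays missing, not zero
  na_counts <- data.frame(item = c("gp_visit", "outpatient_visit"),
                          count = NA_integer_)
  out <- cost_followup(na_counts, uc, "24m")
  expect_true(all(is.na(out)))
  expect_error(cost_followup(data.frame(item = "gp_visit", count = -1L),
                             uc, "15m"), class = "trialcea_validation_error")
  expect_error(cost_followup(counts, uc, "12m"),
               class = "trialcea_validation_error")
})

test_that("discounting follows the annual-bucket convention", {
  led <- data.frame(id = "a", cost_int = 50, pri_3m = 10, sec_3m = 0,
                    pri_15m = 20, sec_15m = 0, pri_24m = 0, sec_24m = 100,
                    pri_36m = 0, sec_36m = 100)
  expect_equal(total_discounted_cost(led, 0), 280)
  expect_equal(total_discounted_cost(led, 0.035),
               round(80 + 100 / 1.035 + 100 / 1.035^2, 2))
  expect_equal(round(total_discounted_cost(led, 0.035) - 80, 2), 189.97)
  # r = 0.06 is the sensitivity configuration and is non-increasing in r
  rs <- c(0, 0.02, 0.035, 0.06)
  tots <- vapply(rs, function(r) total_discounted_cost(led, r), numeric(1))
  expect_true(all(diff(tots) < 0))
  expect_error(total_discounted_cost(led, -0.01),
               class = "trialcea_validation_error")
})

test_that("ledger is additive and NA periods propagate", {
  ds <- generate_trial(small_config(seed = 13))
  led <- cost_ledger(ds, toy_unit_costs())
  r <- 0.035
  manual <- round(led$cost_int + led$pri_3m + led$sec_3m + led$pri_15m +
                    led$sec_15m + (led$pri_24m + led$sec_24m) / (1 + r) +
                    (led$pri_36m + led$sec_36m) / (1 + r)^2, 2)
  expect_equal(total_discounted_cost(led, r), manual)
  miss_rows <- is.na(led$pri_15m)
  expect_true(any(miss_rows))
  expect_true(all(is.na(total_discounted_cost(led, r)[miss_rows])))
  # unoperated patients have no intervention cost
  no_surg <- !ds$patients$surgery_received
  expect_true(all(led$cost_int[no_surg] == 0))
})

test_that("no-surgery zero-cost rule and its relaxation", {
  led <- data.frame(id = c("a", "b", "c"), cost_int = c(0, 0, 500),
                    pri_3m = c(NA, 10, 10), sec_3m = c(NA, 0, 0),
                    pri_15m = NA_real_, sec_15m = NA_real_,
                    pri_24m = NA_real_, sec_24m = NA_real_,
                    pri_36m = NA_real_, sec_36m = c(NA, NA, 40))
  patients <- data.frame(id = c("a", "b", "c"),
                         surgery_received = c(FALSE, FALSE, TRUE))
  # a: no surgery, no follow-up data at all -> secondary zeroed
  out <- apply_no_surgery_cost_rule(led, patients)
  expect_equal(unlist(out[1, paste0("sec_", c("3m", "15m", "24m", "36m"))]),
               c(sec_3m = 0, sec_15m = 0, sec_24m = 0, sec_36m = 0))
  # b: no surgery but some follow-up data -> untouched
  expect_equal(out[2, ], led[2, ], ignore_attr = TRUE)
  # c: had surgery -> untouched
  expect_equal(out[3, ], led[3, ], ignore_attr = TRUE)
  # relaxed: a's secondary costs stay missing for imputation
  rel <- apply_no_surgery_cost_rule(led, patients, relax = TRUE)
  expect_true(all(is.na(rel[1, paste0("sec_", c("3m", "15m", "24m", "36m"))])))
})
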