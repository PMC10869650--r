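# Shared fixtures: small configurations and toy tables built in code.

# A small trial for fast structural tests.
small_config <- function(seed = 11, n_per_arm = 40L, n_centres = 6L, ...) {
  trial_config(n_per_arm = n_per_arm, n_centres = n_centres, seed = seed, ...)
}

# The stated null world: no cost or utility effect, identical baseline
# utility distributions in both arms.
null_config <- function(n_per_arm, seed, ...) {
  trial_config(n_per_arm = n_per_arm, seed = seed,
               true_cost_effect = 0, true_utility_effect = 0,
               baseline_utility_mean = c(0.85, 0.85),
               baseline_utility_sd = c(0.22, 0.22), ...)
}

# Toy unit-cost table: staff-inclusive theatre rate of 10/min carried
# by the surgeon role, all other components free unless priced.
toy_unit_costs <- function(overrides = list()) {
  items <- data.frame(
    item = c("surgeon_per_min", "anaesthetist_per_min",
             "nurse_band5_per_min", "nurse_band4_per_min",
             "theatre_per_min", "device_minisling", "device_standardsling",
             "anaesthesia_general", "anaesthesia_spinal", "anaesthesia_la_iv",
             "anaesthesia_la_oral", "anaesthesia_la_only",
             "recovery_per_min", "ward_day", "catheter",
             "return_to_theatre", "gp_visit", "nurse_visit",
             "physio_visit", "district_nurse_visit", "outpatient_visit",
             "inpatient_day", "further_procedure"),
    unit = "each",
    price = c(10, 0, 0, 0, 0, 100, 100, 0, 0, 0, 0, 0, 0, 0, 0, 0,
              30, 0, 0, 0, 120, 0, 0),
    source = "toy",
    stringsAsFactors = FALSE)
  for (nm in names(overrides)) items$price[items$item == nm] <- overrides[[nm]]
  structure(items, class = c("unit_cost_table", "data.frame"))
}

toy_intervention_record <- function(theatre_minutes = 30,
                                    device_type = "minisling",
                                    device_count = 1L,
                                    anaesthesia = "la_only",
                                    anaesthetist_present = FALSE,
                                    recovery_minutes = 0,
                                    los_days = 0L, catheters = 0L,
                                    return_theatre = FALSE,
                                    consumables_cost = 0) {
  list(theatre_minutes = theatre_minutes, device_type = device_type,
       device_count = device_count, anaesthesia = anaesthesia,
       anaesthetist_present = anaesthetist_present,
       recovery_minutes = recovery_minutes, los_days = los_days,
       n_nurse_band5 = 2L, n_nurse_band4 = 1L, catheters = catheters,
       return_theatre = return_theatre, consumables_cost = consumables_cost)
}

# One-row-per-patient covariate frame for GLM tests.
glm_frame <- function(n, n_centres = 12L, seed = 1) {
  set.seed(seed)
  data.frame(
    arm = sample(rep(c("intervention", "comparator"), length.out = n)),
    u_baseline = runif(n, 0.5, 1),
    pfmt = rbinom(n, 1L, 0.4),
    age = round(rnorm(n, 50, 10)),
    centre = sample.int(n_centres, n, replace = TRUE),
    ui_type = sample(c("SUI", "MUI"), n, replace = TRUE),
    stringsAsFactors = FALSE)
}

# Independent fine-grid oracle for the discounted piecewise-linear AUC:
# trapezoid over a dense grid containing every knot and year boundary,
# with the per-segment annual discount factor.
auc_grid_oracle <- function(time, utility, r, horizon_days = 1095.75) {
  grid <- sort(unique(c(seq(0, horizon_days, length.out = 4001),
                        time[time <= horizon_days], 365.25, 730.5,
                        horizon_days)))
  f <- approx(time, utility, xout = grid, rule = 2)$y
  n <- length(grid)
  a <- grid[-n]; b <- grid[-1]
  k <- floor((a + b) / 2 / 365.25)
  sum((1 + r)^(-k) * (f[-n] + f[-1]) / 2 * (b - a)) / 365.25
}
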