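# Synthetic two-arm multi-centre trial generator.
#
# The generator draws a latent continuous utility per patient and time
# point and converts it to questionnaire item levels through a monotone
# threshold map, draws right-skewed resource use per category and period,
# and applies missing-at-random questionnaire non-return through a
# logistic model on observed covariates with intercepts calibrated per
# time point. All randomness flows from named substreams of the config
# seed so generation and missingness can be varied independently.

# Per-dimension prevalence targets used to calibrate the latent-to-item
# threshold map (share of a treated female SUI population above level 1
# and at the worst level, per EQ-5D-3L dimension).
EQ5D_PREV2 <- c(mobility = 0.15, selfcare = 0.05, activity = 0.20,
                pain = 0.45, anxiety = 0.30)
EQ5D_PREV3 <- c(mobility = 0.02, selfcare = 0.01, activity = 0.03,
                pain = 0.06, anxiety = 0.04)

# Ramp of the target missingness fraction over post-baseline time points;
# the last points reach the configured target, earlier ones are lower
# (questionnaire return decays with time from randomisation).
MISS_RAMP <- c(`4w` = 0.5, `3m` = 0.6, `15m` = 0.9, `24m` = 1.0, `36m` = 1.0)

ANAESTHESIA_TYPES <- c("general", "spinal", "la_iv", "la_oral", "la_only")
PRIMARY_ITEMS <- c("gp_visit", "nurse_visit", "physio_visit",
                   "district_nurse_visit")
SECONDARY_ITEMS <- c("outpatient_visit", "inpatient_day", "further_procedure")

#' Generate a synthetic two-arm trial dataset
#'
#' Draws a complete patient-level dataset with the structure a trial-based
#' cost-utility analysis assumes: 1:1 randomisation across centres, a
#' baseline utility imbalance between arms, latent utility trajectories
#' mapped monotonically to EQ-5D-3L and condition-specific item levels,
#' component-level intervention resource use, right-skewed follow-up
#' resource use, a waiting time to surgery (with a fraction never
#' operated), and missing-at-random questionnaire non-return rising with
#' time since randomisation. The configured arm difference in mean total
#' cost is realised through a consumables component calibrated against
#' the default unit-cost table.
#'
#' @param config a [trial_config()].
#' @return a `trial_dataset`: list of data frames `patients`,
#'   `intervention`, `eq5d`, `iciq`, `resource_use` plus the `config`.
#'   The attribute `"latent"` carries the oracle-only latent utilities
#'   (never serialised; used to test the missing-at-random property).
#' @export
generate_trial <- function(config = trial_config()) {
  stopifnot(inherits(config, "trial_config"))
  full <- with_seed(substream_seed(config$seed, "generation"),
                    gen_complete_data(config))
  ds <- with_seed(substream_seed(config$seed, "missingness"),
                  apply_missingness(full$dataset, config))
  attr(ds, "latent") <- full$latent
  ds
}

# ---- complete-data generation (no missingness) -------------------------

gen_complete_data <- function(config) {
  n <- 2L * config$n_per_arm
  id <- sprintf("P%04d", seq_len(n))
  arm <- sample(rep(c("intervention", "comparator"), config$n_per_arm))
  centre <- sample.int(config$n_centres, n, replace = TRUE)
  centre_u <- stats::rnorm(config$n_centres, 0, 0.02)
  age <- pmin(pmax(round(stats::rnorm(n, 50, 11)), 18), 85)
  pfmt <- stats::rbinom(n, 1L, 0.35)
  ui_type <- sample(c("SUI", "MUI"), n, replace = TRUE, prob = c(0.75, 0.25))
  surgery_received <- stats::rbinom(n, 1L, 1 - config$p_no_surgery) == 1L
  surgery_day <- ifelse(
    surgery_received,
    pmin(pmax(round(stats::rlnorm(n, config$surgery_delay_meanlog,
                                  config$surgery_delay_sdlog)), 1), 420),
    NA_real_)

  ai <- arm == "intervention"
  b_mean <- ifelse(ai, config$baseline_utility_mean[1],
                   config$baseline_utility_mean[2])
  b_sd <- ifelse(ai, config$baseline_utility_sd[1],
                 config$baseline_utility_sd[2])
  b <- stats::rnorm(n, b_mean + centre_u[centre], b_sd)

  # latent utility per schedule point: baseline level plus a modest
  # post-surgery improvement plus the configured arm effect
  eff <- ifelse(ai, config$true_utility_effect, 0)
  latent <- matrix(NA_real_, n, length(EQ5D_TIMES),
                   dimnames = list(id, EQ5D_TIMES))
  latent[, "baseline"] <- b
  for (tp in EQ5D_TIMES[-1]) {
    latent[, tp] <- b + 0.015 * surgery_received + eff +
      stats::rnorm(n, 0, 0.10)
  }

  m_ref <- mean(config$baseline_utility_mean)
  s_ref <- mean(config$baseline_utility_sd)
  eq5d <- do.call(rbind, lapply(EQ5D_TIMES, function(tp) {
    sched <- !(tp %in% c("4w", "3m")) | surgery_received
    items <- eq5d_items_from_latent(latent[sched, tp], m_ref, s_ref)
    data.frame(id = id[sched], time = tp, items,
               stringsAsFactors = FALSE)
  }))

  v_base <- 0.94 + 0.3 * (b - m_ref) + stats::rnorm(n, 0, 0.015)
  iciq <- do.call(rbind, lapply(ICIQ_TIMES, function(tp) {
    v <- if (tp == "baseline") v_base else
      v_base + 0.035 * surgery_received + 0.3 * eff + stats::rnorm(n, 0, 0.01)
    items <- iciq_items_from_latent(v)
    data.frame(id = id, time = tp, items, stringsAsFactors = FALSE)
  }))

  intervention <- gen_intervention(id[surgery_received], ai[surgery_received],
                                   config)
  resource_use <- gen_resource_use(id, centre, config)

  # calibrate the consumables component so the arm difference in mean
  # total cost (intervention components; follow-up is null by design)
  # equals the configured effect under the default unit-cost table
  uc <- default_unit_costs()
  base_cost <- vapply(seq_len(nrow(intervention)), function(i)
    cost_intervention(intervention[i, ], uc), numeric(1))
  int_arm <- ai[match(intervention$id, id)]
  base_diff <- mean(base_cost[int_arm]) - mean(base_cost[!int_arm])
  cons_mean_comp <- 60
  cons_mean_int <- max(5, cons_mean_comp + config$true_cost_effect - base_diff)
  cons_mean <- ifelse(int_arm, cons_mean_int, cons_mean_comp)
  intervention$consumables_cost <- pence(
    stats::rgamma(nrow(intervention), shape = 25, scale = cons_mean / 25))

  ds <- structure(list(
    patients = data.frame(id = id, arm = arm, centre = centre, age = age,
                          pfmt = pfmt, ui_type = ui_type,
                          surgery_received = surgery_received,
                          surgery_day = surgery_day,
                          stringsAsFactors = FALSE),
    intervention = intervention,
    eq5d = eq5d[order(eq5d$id, match(eq5d$time, EQ5D_TIMES)), ],
    iciq = iciq[order(iciq$id, match(iciq$time, ICIQ_TIMES)), ],
    resource_use = resource_use,
    config = config
  ), class = "trial_dataset")
  rownames(ds$eq5d) <- NULL
  rownames(ds$iciq) <- NULL
  list(dataset = ds, latent = latent)
}

# Monotone threshold map: item level rises as a noisy copy of the latent
# utility falls through per-dimension thresholds set at population
# quantiles, so the tariff-valued utility tracks the latent scale.
eq5d_items_from_latent <- function(u, m_ref, s_ref) {
  t2 <- m_ref + s_ref * stats::qnorm(EQ5D_PREV2)
  t3 <- m_ref + s_ref * stats::qnorm(EQ5D_PREV3)
  out <- sapply(seq_along(EQ5D_DIMENSIONS), function(j) {
    lat <- u + stats::rnorm(length(u), 0, 0.05)
    1L + (lat < t2[j]) + (lat < t3[j])
  })
  out <- matrix(as.integer(out), ncol = length(EQ5D_DIMENSIONS))
  colnames(out) <- EQ5D_DIMENSIONS
  out
}

iciq_items_from_latent <- function(v, m_ref = 0.96, s_ref = 0.025) {
  t2 <- m_ref + s_ref * stats::qnorm(0.50)
  t3 <- m_ref + s_ref * stats::qnorm(0.15)
  t4 <- m_ref + s_ref * stats::qnorm(0.03)
  out <- sapply(1:8, function(j) {
    lat <- v + stats::rnorm(length(v), 0, 0.01)
    1L + (lat < t2) + (lat < t3) + (lat < t4)
  })
  out <- matrix(as.integer(out), ncol = 8L)
  colnames(out) <- paste0("item", 1:8)
  out
}

gen_intervention <- function(id, is_intervention, config) {
  k <- length(id)
  an_prob <- function(int) if (int) c(0.20, 0.05, 0.25, 0.20, 0.30)
                           else      c(0.65, 0.15, 0.10, 0.05, 0.05)
  anaesthesia <- vapply(is_intervention, function(int)
    sample(ANAESTHESIA_TYPES, 1L, prob = an_prob(int)), character(1))
  anaesthetist_present <- anaesthesia %in% c("general", "spinal", "la_iv") |
    stats::rbinom(k, 1L, 0.3) == 1L
  theatre_mean <- ifelse(is_intervention, 25, 35)
  theatre_minutes <- round(stats::rgamma(k, shape = 8,
                                         scale = theatre_mean / 8), 1)
  recovery_mean <- ifelse(anaesthesia == "general", 90, 40)
  recovery_minutes <- round(stats::rgamma(k, shape = 4,
                                          scale = recovery_mean / 4), 1)
  data.frame(
    id = id,
    device_type = ifelse(is_intervention, "minisling", "standardsling"),
    device_count = 1L + stats::rbinom(k, 1L, 0.02),
    anaesthesia = anaesthesia,
    anaesthetist_present = anaesthetist_present,
    theatre_minutes = theatre_minutes,
    recovery_minutes = recovery_minutes,
    los_days = stats::rnbinom(k, size = 0.5, mu = 0.4),
    n_nurse_band5 = 2L, n_nurse_band4 = 1L,
    catheters = stats::rbinom(k, 1L, 0.3),
    return_theatre = stats::rbinom(k, 1L, 0.01) == 1L,
    consumables_cost = 0,
    stringsAsFactors = FALSE
  )
}

gen_resource_use <- function(id, centre, config) {
  n <- length(id)
  lam_pri <- c(gp_visit = 1.0, nurse_visit = 0.5, physio_visit = 0.3,
               district_nurse_visit = 0.1)
  lam_sec <- c(outpatient_visit = 0.35, inpatient_day = 0.30,
               further_procedure = 0.02)
  rows <- lapply(COST_PERIODS, function(period) {
    scale <- if (period == "3m") 0.15 else 1
    f <- stats::rgamma(n, shape = config$cost_shape,
                       scale = 1 / config$cost_shape)
    counts <- sapply(c(lam_pri, lam_sec), function(l)
      stats::rpois(n, l * scale * f))
    data.frame(id = rep(id, times = length(c(lam_pri, lam_sec))),
               period = period,
               item = rep(names(c(lam_pri, lam_sec)), each = n),
               count = as.integer(counts),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$id, match(out$period, COST_PERIODS), out$item), ]
  rownames(out) <- NULL
  out
}

# ---- missingness -------------------------------------------------------

# MAR non-return: one indicator per patient and post-baseline time point
# (a non-returned postal questionnaire loses the utility items and, for
# cost periods, the resource-use answers together). Intercepts are
# calibrated so the expected missing fraction matches the ramped target.
apply_missingness <- function(ds, config) {
  if (config$target_missing_fraction == 0) return(ds)
  p <- ds$patients
  bl <- ds$eq5d[ds$eq5d$time == "baseline", ]
  u0 <- value_eq5d(bl[match(p$id, bl$id), EQ5D_DIMENSIONS])
  co <- config$missingness_coefficients
  lp <- co["age"] * (p$age - 50) / 10 +
    co["baseline_utility"] * (u0 - 0.85) +
    co["arm"] * (p$arm == "intervention")
  for (tp in names(MISS_RAMP)) {
    target <- config$target_missing_fraction * MISS_RAMP[[tp]]
    alpha <- stats::uniroot(function(a) mean(stats::plogis(a + lp)) - target,
                            c(-30, 30))$root
    miss <- stats::rbinom(nrow(p), 1L, stats::plogis(alpha + lp)) == 1L
    miss_id <- p$id[miss]
    sel <- ds$eq5d$time == tp & ds$eq5d$id %in% miss_id
    ds$eq5d[sel, EQ5D_DIMENSIONS] <- NA_integer_
    if (tp %in% ICIQ_TIMES) {
      sel <- ds$iciq$time == tp & ds$iciq$id %in% miss_id
      ds$iciq[sel, paste0("item", 1:8)] <- NA_integer_
    }
    if (tp %in% COST_PERIODS) {
      sel <- ds$resource_use$period == tp & ds$resource_use$id %in% miss_id
      ds$resource_use$count[sel] <- NA_integer_
    }
  }
  ds
}

#' @export
print.trial_dataset <- function(x, ...) {
  p <- x$patients
  cat(sprintf("<trial_dataset> %d patients (%d intervention / %d comparator), %d centres\n",
              nrow(p), sum(p$arm == "intervention"),
              sum(p$arm == "comparator"), length(unique(p$centre))))
  cat(sprintf("  surgery received: %d; EQ-5D rows: %d; resource rows: %d\n",
              sum(p$surgery_received), nrow(x$eq5d), nrow(x$resource_use)))
  miss <- mean(is.na(x$eq5d$mobility[x$eq5d$time %in% c("15m", "24m", "36m")]))
  cat(sprintf("  late-time-point utility missingness: %.1f%%\n", 100 * miss))
  invisible(x)
}
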