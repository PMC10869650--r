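#' Configuration for the synthetic trial generator
#'
#' Describes the world the generator draws from: a 1:1 two-arm randomised
#' trial across multiple centres, with a right-skewed cost distribution,
#' a baseline utility imbalance between arms, a waiting time to surgery,
#' and missing-at-random follow-up driven by a logistic model on observed
#' covariates. Defaults emulate a multi-centre UK surgical trial in stress
#' urinary incontinence: 298 women per arm in 21 centres, baseline EQ-5D
#' utilities around 0.86 (intervention) and 0.834 (comparator), and
#' late-follow-up missingness around 45%.
#'
#' @param n_per_arm patients per arm (>= 2).
#' @param n_centres number of recruiting centres (>= 1).
#' @param true_cost_effect arm difference (intervention minus comparator) in
#'   mean total cost, GBP. Default -6.
#' @param true_utility_effect arm difference in mean post-baseline utility
#'   (dimensionless). Default 0.002 (about 0.005 discounted QALYs over
#'   three years).
#' @param baseline_utility_mean,baseline_utility_sd length-2 numeric,
#'   `c(intervention, comparator)`: latent baseline utility moments, used
#'   to emulate chance baseline imbalance.
#' @param surgery_delay_meanlog,surgery_delay_sdlog log-normal parameters of
#'   days from randomisation to surgery.
#' @param p_no_surgery probability a randomised woman never receives surgery.
#' @param cost_shape gamma shape parameter controlling the right skew of
#'   resource-use intensity (smaller is more skewed).
#' @param missingness_coefficients named numeric log-odds per predictor of
#'   questionnaire non-return: `age` (per decade above 50), `baseline_utility`
#'   (per unit above 0.85), `arm` (intervention vs comparator).
#' @param target_missing_fraction target fraction of missing questionnaires
#'   at the latest time points, in `[0, 1)`.
#' @param seed integer master seed.
#' @return an object of class `trial_config`.
#' @export
trial_config <- function(n_per_arm = 298L,
                         n_centres = 21L,
                         true_cost_effect = -6,
                         true_utility_effect = 0.002,
                         baseline_utility_mean = c(0.860, 0.834),
                         baseline_utility_sd = c(0.20, 0.25),
                         surgery_delay_meanlog = log(60),
                         surgery_delay_sdlog = 0.5,
                         p_no_surgery = 0.05,
                         cost_shape = 0.5,
                         missingness_coefficients = c(age = 0.3,
                                                      baseline_utility = -0.8,
                                                      arm = 0.1),
                         target_missing_fraction = 0.45,
                         seed = 1L) {
  check_that(is.numeric(n_per_arm) && length(n_per_arm) == 1L && n_per_arm >= 2,
             "n_per_arm", "must be a single number >= 2")
  check_that(is.numeric(n_centres) && length(n_centres) == 1L && n_centres >= 1,
             "n_centres", "must be a single number >= 1")
  check_that(is.numeric(true_cost_effect) && length(true_cost_effect) == 1L,
             "true_cost_effect", "must be a single number")
  check_that(is.numeric(true_utility_effect) && length(true_utility_effect) == 1L,
             "true_utility_effect", "must be a single number")
  check_that(is.numeric(baseline_utility_mean) && length(baseline_utility_mean) == 2L,
             "baseline_utility_mean", "must be length-2 numeric (intervention, comparator)")
  check_that(is.numeric(baseline_utility_sd) && length(baseline_utility_sd) == 2L &&
               all(baseline_utility_sd > 0),
             "baseline_utility_sd", "must be length-2 positive numeric")
  check_that(is.numeric(p_no_surgery) && length(p_no_surgery) == 1L &&
               p_no_surgery >= 0 && p_no_surgery <= 1,
             "p_no_surgery", "must be a probability in [0, 1]")
  check_that(is.numeric(cost_shape) && cost_shape > 0,
             "cost_shape", "must be > 0")
  check_that(is.numeric(target_missing_fraction) &&
               length(target_missing_fraction) == 1L &&
               target_missing_fraction >= 0 && target_missing_fraction < 1,
             "target_missing_fraction", "must be in [0, 1)")
  check_that(is.numeric(missingness_coefficients) &&
               all(c("age", "baseline_utility", "arm") %in%
                     names(missingness_coefficients)),
             "missingness_coefficients",
             "must be named numeric with age, baseline_utility, arm")
  check_that(is.numeric(seed) && length(seed) == 1L && is.finite(seed),
             "seed", "must be a single finite number")
  structure(list(
    n_per_arm = as.integer(n_per_arm),
    n_centres = as.integer(n_centres),
    true_cost_effect = true_cost_effect,
    true_utility_effect = true_utility_effect,
    baseline_utility_mean = baseline_utility_mean,
    baseline_utility_sd = baseline_utility_sd,
    surgery_delay_meanlog = surgery_delay_meanlog,
    surgery_delay_sdlog = surgery_delay_sdlog,
    p_no_surgery = p_no_surgery,
    cost_shape = cost_shape,
    missingness_coefficients = missingness_coefficients,
    target_missing_fraction = target_missing_fraction,
    seed = as.integer(seed)
  ), class = "trial_config")
}

#' @export
print.trial_config <- function(x, ...) {
  cat("<trial_config>\n")
  cat(sprintf("  n per arm: %d across %d centres (seed %d)\n",
              x$n_per_arm, x$n_centres, x$seed))
  cat(sprintf("  true effects: cost %+.1f GBP, utility %+.4f\n",
              x$true_cost_effect, x$true_utility_effect))
  cat(sprintf("  baseline utility: %.3f (sd %.2f) vs %.3f (sd %.2f)\n",
              x$baseline_utility_mean[1], x$baseline_utility_sd[1],
              x$baseline_utility_mean[2], x$baseline_utility_sd[2]))
  cat(sprintf("  target late missingness: %.0f%%\n",
              100 * x$target_missing_fraction))
  invisible(x)
}
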