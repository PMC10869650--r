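---
title: "Methods: trial-based cost-utility analysis with trialcea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trial-based cost-utility analysis with trialcea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions and design choices in
`trialcea`, in the spirit of the methods sections of the mature
analysis packages: what is computed, under which assumptions, which
knobs matter, and what a green test does and does not establish.

## The estimand and the pipeline

The package targets the standard within-trial cost-utility estimand
for a two-arm, multi-centre RCT over a 36-month horizon from a health
service perspective: the adjusted incremental cost ΔC and incremental
QALYs ΔE of the intervention versus the comparator, the ICER ΔC/ΔE
with dominance-quadrant labelling, and the probability of
cost-effectiveness at a willingness-to-pay λ via the net monetary
benefit λ·ΔE − ΔC. A full run is

valuation → QALY AUC → micro-costing → missingness diagnosis →
multiple imputation → adjusted GLMs → Rubin pooling → cluster
bootstrap → ICER / CEAC → sensitivity suite,

orchestrated by `run_cua()` and `run_sensitivity_suite()`.

## Utility valuation

EQ-5D-3L states are valued additively: utility = 1 − c·1[any level>1]
− Σ per-dimension level decrements − n3·1[any level=3]. The shipped
default is the UK general-population time-trade-off value set
(c = 0.081, n3 = 0.269), under which the best state values to exactly
1 and the worst to −0.594. Valuation is monotone non-increasing in
every item level — property-tested over all 243 states — because
decrements are non-negative and non-decreasing in level, which the
`utility_tariff()` constructor enforces on any user-supplied table.

The condition-specific instrument is valued through a mapping of the
same additive shape. The published mapping algorithm's coefficients
are not reproduced in the source literature available to this package,
so the default (`iciq_mapping_synthetic()`) is an explicitly synthetic
stand-in calibrated to the narrow 0.94–0.99 band such instruments
produce in treated populations; it is configuration, labelled
synthetic in both filename and documentation, and pluggable via
`read_tariff()`.

A response with any missing item yields a missing utility rather than
an error: item-level incompleteness is a missing-data problem, handled
downstream by imputation.

## QALYs: area under the curve, anchoring, discounting

`qaly_auc()` integrates the piecewise-linear curve through the
observed (time, utility) points. Conventions, each with a rationale:

- **Time anchoring.** Baseline at day 0; the 4-week and 3-month
  questionnaires are anchored to the surgery date (surgery day + 28 /
  + 91); the 15-, 24- and 36-month questionnaires to randomisation
  (456 / 730 / 1096 days). Days since randomisation is the integration
  axis. With a late surgery the two anchor systems can interleave;
  points are integrated in time order, with the surgery-wait override
  taking precedence over any point observed before surgery.
- **Surgery-wait adjustment** (default on): utility is held flat at
  the baseline value on [0, surgery day] — patients cannot accrue
  surgical QALY gains while waiting. Turning it off (sensitivity
  analysis) gives the plain trapezoid. Patients who never receive
  surgery contribute baseline and the 15/24/36-month points only, the
  4-week/3-month questionnaires being structurally absent rather than
  missing.
- **Discounting** follows annual accrual buckets: QALYs accrued in
  months (12, 24] are multiplied by (1+r)^−1 and in (24, 36] by
  (1+r)^−2, with r = 0.035 by default (0–0.06 in sensitivity
  analyses). Continuous-time discounting was rejected: the year-bucket
  convention is what "year 2 and 3 discounted" means in trial reports,
  and it reproduces the closed forms 1 + 1/1.035 + 1/1.035² = 2.8997
  QALYs for constant full health and £189.97 for £100 in each of
  years 2 and 3.
- **No extrapolation.** A trajectory whose last observation precedes
  the horizon returns `NA` — late-time-point absence is missing data
  for the imputation model, not a truncation problem to be solved by
  carrying values forward. A trajectory that is entirely missing is an
  error ("impute first"), since reaching that state indicates a
  pipeline misuse.
- Utilities below 0 are allowed (the tariff range extends to −0.594);
  utilities are capped at 1. Note that discounting is monotone
  QALY-decreasing only for non-negative trajectories; with negative
  utilities a discounted year can contribute *less negatively*. The
  tests assert monotonicity on the non-negative subset for this
  reason.

## Costing

`cost_intervention()` micro-costs the index operation bottom-up:
theatre minutes × (surgeon + anaesthetist-if-present + two band-5 and
one band-4 nurse + theatre overhead, all per minute) + device list
price × count + anaesthesia drug cost by type + recovery minutes +
ward days + catheters + return-to-theatre + consumables. A "no"
answer to a follow-up resource question is a zero count and costs
zero; an unanswered questionnaire leaves the sector cost missing for
imputation — `cost_followup()` keeps this distinction explicit.
Ledger arithmetic is held at pence precision (`round(x, 2)` at every
aggregation), and period costs are discounted on the same annual
buckets as QALYs, assigned by questionnaire label: 3- and 15-month
periods undiscounted, 24-month × (1+r)^−1, 36-month × (1+r)^−2. The
15-month period straddles the year boundary; leaving it undiscounted
follows the reporting convention that names only years 2 and 3 as
discounted, and is documented here as a convention rather than a
claim.

Patients who never had surgery and returned no follow-up forms are
assumed to have zero secondary-care costs (they never re-engaged with
hospital services); `apply_no_surgery_cost_rule(relax = TRUE)` drops
the assumption and sends those cells to imputation instead
(sensitivity analysis 5).

Unit prices are entirely configuration (`read_unit_costs()`); the
shipped CSV is a plausible 2018/2019-style NHS table but synthetic,
and is named accordingly.

## Missing data

`missingness_model()` fits one logistic regression per analysis
variable of the missing indicator on age, PFMT, baseline utility,
baseline incontinence type and arm, and flags multiple imputation when
any cost or QALY variable exceeds 5% missingness. Structurally absent
cells (the 4-week/3-month questionnaires of unoperated patients) are
excluded via the `eligible` argument — they are not missing data and
must not trigger imputation on an otherwise complete dataset.

`impute_pmm()` implements predictive mean matching with proper
parameter draws: per imputation, σ² is drawn from its scaled
inverse-χ² posterior and β from N(β̂, σ²(XᵀX)⁻¹); predictions for
observed cases use β̂ and for missing cases β* (type-1 matching); each
missing case copies the observed value of one donor drawn uniformly
from its knn = 5 nearest predictions, equidistant donors all entering
the pool. Proper draws were chosen so Rubin's-rules variances are
valid; `proper = FALSE` gives deterministic-parameter PMM for
comparison. Imputed values therefore always lie in the observed
support, which the tests assert.

Imputation operates at the granularity the analysis consumes —
time-point utilities and period-level sector costs, not item-level
responses — keeping the predictor matrix well conditioned. The
predictor set is the complete baseline block (arm, age, PFMT, baseline
utility, incontinence type); within a variable group, targets are
processed in order of increasing missingness and completed variables
join the predictor set of later ones, a monotone-style sequential pass
that lets information flow across time points without full chained
equations (which are out of scope). m = 20 and knn = 5 by default,
both configurable.

`rubins_pool()` applies the standard rules (pooled mean; total
variance W̄ + (1+1/m)B; Barnard–Rubin-style small-sample df;
t-interval), degrading gracefully at m = 1.

## Models and inference

`fit_glm()` fits outcome ~ arm + baseline QoL + PFMT + age by IRLS
with families Gaussian, Poisson-type (quasi-likelihood, variance ∝
mean — valid for continuous outcomes), Gamma and inverse Gaussian,
identity or log link. Centre enters the variance only: the covariance
is a cluster-robust sandwich (scores summed within centres, G/(G−1)
correction), reducing to the heteroscedasticity-robust form with
singleton clusters. The inverse-Gaussian IRLS is numerically fragile
from R's default start on exactly the variance ∝ mean³ data it suits;
it is seeded with same-link Gamma coefficients, without which the
canonical cost-family selection is unreachable in practice.

Family selection follows the modified Park test — a Gamma/log GLM of
squared raw residuals on log fitted means, whose slope λ indexes
variance ∝ mean^λ: 0 Gaussian, 1 Poisson-type, 2 Gamma, 3 inverse
Gaussian — cross-checked against minimum AIC (undefined for the
quasi-family and reported as such), the Park recommendation winning
on disagreement, with the full decision table returned. Link choice
counts passes among the Pregibon test (squared linear predictor
refit), a modified Hosmer–Lemeshow F-test of mean raw residuals
across fitted-value deciles (groups reduced with a warning when
fitted values tie), and the Pearson correlation test of raw residuals
against fitted values.

Incremental means use recycled predictions (predict everyone under
each arm; difference the means), which for the identity link equals
the arm coefficient to machine precision. Interval options: the
cluster-robust delta method with t(G−1) quantiles (exact for identity
links), or a nonparametric bootstrap over centres — the default for
non-identity links, aligning the resampling unit with the clustering.
Zero-valued cost totals (possible for unoperated non-responders under
the zero-cost rule) exclude the positive-support families from the
candidate set rather than being shifted or dropped.

## Bootstrap CEA

`bootstrap_cea()` combines imputation and sampling uncertainty in a
single loop: each replicate samples one completed dataset uniformly,
resamples centres with replacement (relabelling copies so a centre
drawn twice contributes two clusters), and records the estimator's
(ΔC, ΔE). The single-loop scheme is unbiased for the MI-mixture
distribution at a fraction of the nested-loop cost; patient-level
resampling is available as an option. Failed replicates are dropped
with a message, aborting beyond 5%. `ceac()` is the fraction of draws
with positive net benefit; the comparator curve is the exact
complement. The CEAC is *not* monotone in λ in general (draws in the
southwest quadrant gain net benefit as λ falls), so the tests assert
bounds, the complement identity and the λ → 0 / λ → ∞ quadrant
limits instead. Southwest ICERs are labelled "cost saving per QALY
lost", where a ratio above the threshold favours the intervention —
the reversed decision rule that quadrant requires.

Default B = 2000 and a £0–50 000 grid in £500 steps including the
£20 000 and £30 000 decision thresholds.

## The synthetic generator: what it emulates, and what not

`generate_trial()` draws the world the analysis assumes, with defaults
fixed to the emulated trial: 298 per arm across 21 centres; latent
baseline utilities N(0.860, 0.20) / N(0.834, 0.25) (the intervention /
comparator baseline imbalance); a log-normal ~60-day wait for surgery
with 5% never operated; heavy-right-tail resource use via a
gamma-mixed Poisson (shape 0.5); true effects of −£6 total cost and
+0.002 utility (≈ +0.005 discounted QALYs over three years); and
missing-at-random postal non-response driven by age, baseline utility
and arm, with per-time-point intercepts calibrated by root-finding so
realised rates ramp up to the 45% target at late time points. One
master seed feeds named substreams (generation, missingness,
imputation, bootstrap) so components vary independently.

Questionnaire items are produced from the latent utility by a
monotone threshold map: per dimension, a noisy copy of the latent
value falls through thresholds placed at population quantiles of
plausible dimension prevalences. This makes tariff-valued utilities
track the latent scale but not affinely — the tariff's constants
compress healthy states to exactly 1 and expand sick tails — so
configured moments are matched approximately, and a configured
baseline *imbalance* re-emerges amplified on the valued scale. Tests
therefore assert structure (direction of imbalance, missingness
rates, skewness, MAR-ness — the latent values are exposed as an
oracle-only attribute precisely so tests can verify that missingness
carries no signal beyond observed covariates) rather than exact
moments.

Known departures from real trial data, by design: per-time-point
missingness is targeted (real reports suggest lower marginal rates
with the 43–47% figure describing joint complete-case loss; the joint
pattern here is a modelling choice, and the resulting complete-case
fraction is lower than the emulated trial's); follow-up cost
distributions are identical across arms (the entire cost effect lives
in the intervention components, realised through a consumables
component calibrated against the default unit-cost table); clinical
events appear only through their cost and quality-of-life footprint;
and randomisation is simple 1:1 rather than minimisation. A green
end-to-end test establishes that the pipeline is internally coherent
and calibrated under this stated world — not that it reproduces any
particular trial's numbers.

## Null calibration and its statistics

One acceptance test checks end-to-end null calibration: in a
zero-effect world (equal baseline distributions, zero cost and
utility effects) the probability of cost-effectiveness at £20 000
should be near one half. A subtlety worth recording: for a *single*
simulated trial the CEAC value is approximately Φ(z) of the trial's
point estimate against its own bootstrap standard error — a
Uniform(0,1) variable under the null. The criterion is therefore a
statement about the average over trials, and the test asserts that
the mean over 15 replicate scaled pipelines (200 per arm, m = 5,
B = 500, fixed seeds) lies in [0.4, 0.6]; the cost family is fixed at
Gaussian/identity there to keep 7 500 bootstrap refits robust.

## Numerical conventions and degenerate inputs

Currency at pence precision in ledgers, floating point in model
estimation, whole pounds in reports; utilities to three decimals.
Validation failures raise a classed condition
(`trialcea_validation_error`) naming the field; file-level schema
violations name the offending patient, time point and column.
Datasets round-trip exactly through the long-CSV + JSON-sidecar
format. Determinism contracts (same seed → byte-identical datasets,
identical draws, identical report bundles) are enforced by test.

## Limitations

No two-part/hurdle cost models, mixed effects, multi-comparator
frontiers, value-of-information analysis, or lifetime extrapolation —
all out of scope. The shipped unit-cost and condition-specific
mapping tables are synthetic stand-ins; substantive applications must
supply their own. Cluster-robust inference with ~21 clusters relies
on t(G−1) quantiles, which is serviceable but not exact; wild-cluster
methods are not implemented.
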