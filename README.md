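# trialcea

Trial-based cost-utility analysis for two-arm, multi-centre randomised
controlled trials, written for health economists who need a reusable,
tested pipeline from patient-level trial records to incremental costs,
QALYs, ICERs, cost-effectiveness planes and acceptability curves.

The package grew out of the within-trial economic evaluation of a
surgical trial in female stress urinary incontinence (two sling
procedures, 21 UK centres, ~298 women per arm, 36-month follow-up), and
implements that analysis style end to end:

- **Utility valuation.** EQ-5D-3L responses are valued with the UK
  general-population tariff (additive decrements with the
  any-dysfunction and worst-level constants; the all-ones state values
  to exactly 1 and the worst state to −0.594). A condition-specific
  questionnaire is valued through a pluggable additive mapping.
- **QALYs.** Area under the piecewise-linear utility curve over 36
  months, with utility held flat at baseline until surgery (women
  cannot accrue surgical QALY gains while waiting), and QALYs accrued
  in year *k* discounted by (1 + r)^−(k−1) at r = 3.5% per annum.
- **Costs.** Component micro-costing of the index operation (staff
  minutes, theatre time, device list price, anaesthesia drugs,
  recovery, stay, catheters, returns to theatre) plus per-period
  primary/secondary care costs from resource-use counts × unit prices,
  discounted on the same annual buckets. Unit costs are configuration;
  the shipped table is synthetic and clearly labelled as such.
- **Missing data.** Missingness diagnosed by logistic regression on
  baseline covariates; multiple imputation by predictive mean matching
  (knn = 5, m = 20, proper parameter draws) pooled with Rubin's rules.
- **Models.** Covariate-adjusted GLMs (arm, baseline quality of life,
  PFMT, age) with family selection by the modified Park test
  (variance ∝ mean^λ; λ≈3 → inverse Gaussian, the usual outcome for
  cost data) cross-checked against AIC, link choice by Pregibon,
  modified Hosmer–Lemeshow and Pearson diagnostics, and cluster-robust
  (by centre) sandwich standard errors. Incremental means by recycled
  predictions.
- **Decision analysis.** Non-parametric bootstrap (centres resampled,
  one imputation sampled per replicate) of the joint (ΔC, ΔQALY)
  distribution; ICER with dominance-quadrant labelling; net monetary
  benefit λ·ΔE − ΔC; CEACs over a £0–50 000 willingness-to-pay grid;
  and the standard five-variant sensitivity suite (complete case, no
  surgery-wait adjustment, condition-specific utilities, 6% discount
  rate, relaxed zero-cost rule for unoperated non-responders).
- **Synthetic trials.** Because trial datasets of this kind are rarely
  deposited, a generator reproduces the statistical structure the
  analysis assumes — 1:1 randomisation across centres, baseline
  utility imbalance, right-skewed costs, rising missing-at-random
  non-response reaching ~45% at late time points — so the entire
  pipeline runs and is tested with no external data.

## Worked example

```r
library(trialcea)
cfg <- trial_config(seed = 2024)      # the default emulated trial
ds  <- generate_trial(cfg)
res <- run_cua(ds, m = 10, B = 1000, seed = 2024)
print(res)
```

```
<trial_dataset> 596 patients (298 intervention / 298 comparator), 21 centres
  surgery received: 568; EQ-5D rows: 3520; resource rows: 16688
  late-time-point utility missingness: 42.0%
<cea_result>
  n analysed: 596 (multiple imputation, m = 10)
  cost model: gaussian family, identity link
  incremental cost:  GBP 19 [-138, 176]
  incremental QALYs: -0.004 [-0.070, 0.061]
  ICER: intervention dominated
  P(cost-effective) at GBP 0 / 20k / 30k: 40% / 41% / 41%
```

Read as: after imputing the ~42% late-follow-up non-response and
adjusting for baseline utility, PFMT and age with centre-clustered
errors, the intervention costs £19 more [95% CI −138, 176] and yields
0.004 fewer QALYs [−0.070, 0.061] than the comparator over 36 months —
differences indistinguishable from zero (the generator's true effects
are −£6 and +0.002 utility), equivalent to about a day and a half of
full health, with a 41% probability of being the cost-effective option
at £20 000 per QALY. `run_sensitivity_suite(ds, ...)` appends the five
standard sensitivity rows, and `qalys_to_days()` converts QALY
increments to days of full health.

A command-line interface wraps the same pipeline:

```sh
Rscript inst/cli/trialcea simulate    --config cfg.json --out run/
Rscript inst/cli/trialcea analyse     --config cfg.json --out run/
Rscript inst/cli/trialcea sensitivity --config cfg.json --out run/
```

writing `dataset.csv`, descriptive cost/quality-of-life tables, the
cost-effectiveness plane and CEAC as CSV, a JSON summary, and a log of
every setting and seed.

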