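# psmatchdr

Monte Carlo machinery for a question every analyst of propensity-score
(PS) matched studies faces: **after matching, which residually imbalanced
covariates must be adjusted for by regression, and at what standardized
mean difference (SMD) threshold?**

PS matching rarely balances everything. Residual imbalance in a matched
sample can be corrected by *double-adjustment*: fit a logistic outcome
model within each matched arm on the still-unbalanced covariates, predict
both potential-outcome probabilities for the matched treated units, and
average their difference

```
ATT_DR = (1/J) Σ_j [ p̂_j(Y1=1 | Z=1) − p̂_j(Y0=1 | Z=1) ]
```

against the crude matched estimator `ATT_crude = (1/J) Σ_j (Y_j1 − Y_j0)`.
With scarce events not every covariate can enter the regression, so
covariates are selected by an SMD cutoff,

```
SMD_i = |W̄_i1 − W̄_i0| / sqrt((s²_i1 + s²_i0) / 2),
```

and the package evaluates all 25 cutoffs 0.01, 0.02, …, 0.25. It is aimed
at biostatisticians and epidemiologists who want to reproduce, stress or
extend this threshold analysis on virtual cohorts.

The package provides:

* **Synthetic perioperative cohorts** — 15 covariates (mixed
  binary/continuous, built from 14 correlated latent normals plus one
  composite risk index), binary treatment (40% exposed) and outcome (8%
  prevalence) from logistic models in two flavors: scenario A (linear,
  additive) and scenario B (non-linear, non-additive, with root/log/power
  and interaction terms). Conditional treatment effect γ_Z = −0.51
  (odds ratio 0.60, protective); true ATT −0.04 on the risk-difference
  scale. Intercepts are calibrated to the marginal targets; everything is
  configurable via code or YAML.
* **Propensity matching** — main-effects logistic PS model and greedy 1:1
  nearest-neighbor matching without replacement or caliper (complete
  matching: ~80% of subjects retained at 40% exposure).
* **Balance diagnostics** — per-covariate SMDs in the matched sample and
  threshold selection.
* **ATT estimators** — crude and double-robust, on the risk-difference
  scale with an optional marginal odds ratio.
* **Study runner** — N replicates × scenarios × (crude + 25 thresholds),
  reporting relative bias, MSE, estimate percentiles and percentages of
  estimates deviating >25/50/75/100% from the truth, plus ggplot2
  summaries and CSV outputs. A thin CLI lives in `inst/scripts/psmatchdr`.

## Worked example

```r
library(psmatchdr)

spec <- default_scenario("A")            # shipped calibrated defaults
cohort <- generate_cohort(5000, spec, seed = 42)
cohort
#> Cohort (scenario A): 5000 units, 2070 treated (41.4%), outcome prevalence 8.2%

fit <- fit_propensity(cohort)
matched <- nearest_neighbor_match(fit$ps_hat, cohort$Z, seed = 43)
retained_fraction(matched, 5000)
#> [1] 82.8

bal <- balance_table(cohort, matched)
head(bal[order(-bal$smd), c("covariate", "mean_treated", "mean_control", "smd")], 6)
#>    covariate mean_treated mean_control   smd
#> 7         W7        0.313       0.0859 0.248
#> 1         W1        0.388       0.2947 0.199
#> 2         W2        0.271       0.1923 0.186
#> 11       W11        1.220       1.1382 0.131
#> 6         W6        0.420       0.3594 0.124
#> 8         W8        0.143       0.0255 0.118

crude_att(matched, cohort$Y)
#> Crude matched ATT: risk difference -0.0145

unbalanced <- select_unbalanced(bal, 0.10)
double_robust_att(matched, cohort, unbalanced, threshold = 0.10)
#> Double-robust ATT: risk difference -0.0430 (threshold 0.1, 6 adjusted covariate(s))
```

The true ATT here is about −0.043: the crude matched estimate (−0.0145)
is badly confounded by the residual imbalance visible in the balance
table, while double-adjustment for the six covariates with SMD ≥ 0.10
recovers the effect. The full experiment across all thresholds:

```r
study <- run_study(study_config(n_replicates = 200, scenarios = "A", seed = 1))
study
#> Monte Carlo study: 200 replicates x 5000 units; scenarios A
#>   A: true ATT -0.0426 | crude rel. bias 66.5% | min MSE 1.54e-04 at threshold 0.08
plot_mse(study)
```

Across replicates the crude estimator stays systematically biased,
double-adjustment at thresholds ≤ 0.10 removes nearly all bias, and the
MSE over the grid bottoms out near a threshold of 0.10 — stricter
selection buys no further bias reduction but costs precision, laxer
selection lets confounders escape adjustment. See the methods vignette
(`vignettes/double-adjustment.Rmd`) for the model, the design of the
default coefficients and known limitations.

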