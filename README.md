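# strokeITE

Causal effect and individualized treatment effect (ITE) estimation for
stroke-prevention cohorts.

## The problem

High-risk patients — with hypertension (HT), diabetes (DM), dyslipidemia
(DLP) or atrial fibrillation (AF) — are followed in observational hospital
cohorts where antiplatelet therapy is prescribed by indication, not at
random. Two questions drive the analysis:

1. **How much does each risk factor raise stroke risk causally?** Estimated
   as the average causal risk difference `E[Y(x=1)] − E[Y(x=0)]` (and risk
   ratio), identified through backdoor adjustment on a clinical causal
   diagram and estimated by a battery of mutually checking methods:
   propensity-score stratification, inverse probability weighting (IPW),
   doubly robust augmented IPW, cross-fitted double machine learning (DML,
   linear and gradient-boosted variants), mediation decomposition into
   natural direct and indirect effects (NDE/NIE), and Dragonnet — a
   three-headed neural network predicting both potential outcomes
   `Ŷ(1), Ŷ(0)` and the propensity `ε̂` from a shared representation
   `φ(X)`, with targeted regularization.

2. **Which untreated patients would benefit from antiplatelet therapy?**
   The per-patient effect `Y(1) − Y(0)` is never observed, so the package
   produces distribution-free intervals for it by nested weighted
   split-conformal quantile regression: per-arm quantile regressors with
   pinball loss, conformity scores reweighted by `1/e(x)` or `1/(1−e(x))`
   against the covariate shift between treatment arms, and a second
   "nested" conformalization that turns per-patient counterfactual bounds
   into ITE intervals valid at level `1 − α` (default 95%).

Because the motivating hospital records cannot be shipped, the package is
built around a structural-causal-model cohort simulator
(`generate_cohort()`) calibrated to the cohort characteristics it emulates — 3.5%
marginal stroke incidence; stratum rates 13%/2% by AF, 4%/1% by HT, 4%/3%
by DM and DLP — that also emits exact per-patient potential outcomes.
Every estimator is validated against that ground truth.

## Worked example

```r
library(strokeITE)

spec <- default_cohort_spec(n = 20000, seed = 42)
sim  <- generate_cohort(spec)
sim
#> synthetic_cohort: n = 20000 | incidence 0.036 | treated 0.428 | mean true ITE -0.0247

# causal risk difference of atrial fibrillation, backdoor-adjusted
adj <- backdoor_adjustment_set(stroke_dag(), "af", "y")   # {age, ht}
ipw_ate(sim$cohort, "af", adj, ci = TRUE, B = 200, seed = 42)
#> ipw [af] risk-difference: 0.07756 (95% CI 0.06437 to 0.09022)
```

AF raises absolute stroke risk by about 7.8 percentage points in this
cohort — the generator's true value is 0.074 — while the same call for DLP
gives an estimate near zero. Mediation splits hypertension's effect into
its direct pathway and the part flowing through kidney disease and atrial
fibrillation:

```r
mediation_effects(sim$cohort, "ht")
#> mediation_effects for 'ht' via {af, ckd}:
#>   NDE   +0.01185
#>   NIE   +0.00782
#>   total +0.01966
```

Dragonnet estimates the antiplatelet treatment effect (doubly robust
correction from its own propensity head), and the conformal module wraps
every patient's predicted effect in a 95% interval:

```r
model <- fit_dragonnet(sim$cohort, config = dragonnet_config(seed = 42))
preds <- predict_potential_outcomes(model, sim$cohort)
dragonnet_ate(preds, sim$cohort)
#> dragonnet [t] risk-difference: -0.02835      # truth: -0.0247

iv <- nested_ite_intervals(sim$cohort,
                           conformal_config(outcome = "y_latent", seed = 42),
                           point = preds$y1_hat - preds$y0_hat)
stratified_ite_summary(iv, sim$cohort)
#>     stratum    n mean_ite   iqr_low iqr_high
#> 7 ht+dm+dlp 2218 -0.05276 -6.15e-02 -0.02053
#> 6     ht+dm 2281 -0.03878 -4.69e-02 -0.01250
#> 2        dm  564 -0.01084 -1.73e-02 -0.00231
#> ...
#> 4        ht 2253  0.01020 -8.34e-05  0.02140
```

The treatment is protective on average (risk difference about −0.028), and
the stratified summary of untreated patients shows the benefit
concentrating in the diabetic strata — patients with DM, and especially DM
with HT, have the most negative mean ITEs, so they are the ones a
clinician would prioritize for antiplatelet therapy. `plot()` on the
summary draws the box plot; `run_full_analysis(analysis_config(...))` runs
the whole battery (all exposures × all estimators, mediation, ITE
analysis) and writes tidy CSVs plus a JSON run manifest.

## Package layout

| Area | Entry points |
| --- | --- |
| Synthetic cohorts | `cohort_spec`, `default_cohort_spec`, `generate_cohort`, `ground_truth_effects`, `export_cohort` |
| Causal diagram | `stroke_dag`, `causal_dag`, `d_separated`, `backdoor_adjustment_set`, `default_estimands` |
| Classical estimators | `fit_propensity`, `sps_ate`, `ipw_ate`, `dre_ate`, `logistic_or_baseline`, `bootstrap_ci` |
| Double machine learning | `dml_config`, `dml_ate` |
| Mediation | `mediation_effects` |
| Dragonnet | `dragonnet_config`, `fit_dragonnet`, `predict_potential_outcomes`, `dragonnet_ate`, `cate`, `causal_risk_ratio` |
| Conformal ITE | `conformal_config`, `fit_quantile_bounds`, `weighted_conformal_counterfactual`, `nested_ite_intervals`, `stratified_ite_summary` |
| Orchestration | `analysis_config`, `run_full_analysis`, `effect_comparison_table` |

The methods vignette (`vignettes/stroke-causal-methods.Rmd`) documents the
models, the generator calibration, all tunable parameters and the design
decisions in detail.
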