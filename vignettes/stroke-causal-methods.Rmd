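---
title: "Causal effects and individualized treatment effects for stroke prevention: methods"
author: "strokeITE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Causal effects and individualized treatment effects for stroke prevention: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokeITE)
```

# The scientific problem

Observational hospital cohorts record which high-risk patients (with
hypertension, diabetes, dyslipidemia or atrial fibrillation) went on to have
a stroke, and which of them were receiving antiplatelet therapy.  Two
questions matter clinically: *how much does each risk factor raise stroke
risk causally*, once confounding is removed, and *which individual untreated
patients would benefit most from antiplatelet therapy*.  The second question
asks for individualized treatment effects (ITEs) — fundamentally
unobservable for any single patient, since only one potential outcome is
ever seen — so honest uncertainty quantification is as important as the
point estimate.

strokeITE implements the full analysis tool-chain for these questions:
average-effect estimators from classical propensity-score methods through
cross-fitted double machine learning and a three-headed neural
potential-outcome network (Dragonnet), mediation decomposition on the
clinical causal diagram, and nested weighted split-conformal quantile
regression for per-patient ITE intervals with a finite-sample marginal
coverage guarantee.  Because real hospital records cannot be redistributed,
the package is organized around a structural-causal-model cohort simulator
with exact per-patient ground truth; every estimator is validated against
that ground truth.

# The causal diagram

`stroke_dag()` encodes the assumed clinical structure.  Age, sex and BMI are
exogenous.  Diabetes (dm) and dyslipidemia (dlp) precede hypertension (ht);
ht precedes chronic kidney disease (ckd) and atrial fibrillation (af);
antiplatelet treatment (t) is prescribed on the basis of ht, dm, dlp and age
(confounding by indication); stroke (y) is terminal.  Thus ht acts on stroke
partly through ckd and af, dm through ht and ckd, and dlp through ht.

Identification is purely graphical: `backdoor_adjustment_set()` searches for
the smallest covariate set that blocks every backdoor path, judged by a
Bayes-ball d-separation routine, with a lexicographic tie-break so results
are deterministic.  On the default diagram the four estimands come out as

```{r estimands, eval = FALSE}
default_estimands()
#> ht:  P(stroke | ht, age, dlp, dm)
#> af:  P(stroke | af, age, ht)
#> dlp: P(stroke | dlp, age)
#> dm:  P(stroke | dm, age, bmi)
```

Two structural choices deserve a note.  Sex is kept as an isolated covariate
node: the diagram gives it no direct edge into stroke, and the adjustment
sets do not change either way.  BMI is given edges into dm and into y — the
dm estimand adjusts for BMI, which is only coherent if BMI confounds the
dm–stroke relation, so the diagram assumes those two edges.

# The synthetic cohort generator

`generate_cohort()` samples patients from logistic structural equations in
topological order.  Continuous parents enter standardized, `(age - 62)/12`
and `(bmi - 25)/4`, so coefficients are log-odds per standard deviation.

**Exogenous distributions.** age ~ Normal(62, 12) truncated below 18 (adult
cohort eligibility; the mean is consistent with stroke patients averaging
about 65), sex ~ Bernoulli(0.5), BMI ~ Normal(25, 4) kg/m².  These are
plausibility choices for an Asian hospital population and are exposed in the
specification object rather than hard-coded.

**Calibration.** The committed default coefficients were fixed once by a
damped fixed-point search (two million simulated patients per iteration):
node intercepts target the implied risk-factor prevalences (af 13.6%, ht
83.3%, dm and dlp 50% — the values consistent with the stratified rates
below), the outcome intercept targets the 3.5% marginal stroke incidence,
and the outcome slopes target the stratified rate ratios 13%/2% (af),
4%/1% (ht), 4%/3% (dm), 4%/3% (dlp).  The committed constants reproduce all
of these within a tenth of a percentage point at large n.

**Treatment.** Assignment depends on ht (+0.80), dm (+0.20), dlp (+0.20)
and age (+0.40 per SD) around a −1.2 intercept; over the support of the
covariates the propensity stays inside (0.05, 0.95), so positivity holds by
construction.  The treatment effect on the outcome log-odds is
`-0.10 - 1.00*dm - 0.15*ht`: protective everywhere, strongest for diabetic
patients.  On the probability scale the true mean ITE is about −0.001 for
patients with neither condition, −0.010 for dm only, −0.008 for ht only and
−0.046 for dm+ht, so the diabetic strata benefit most — the heterogeneity
signal the conformal module is asked to detect.  Two dials were chosen
deliberately here: the dm→t and dlp→t assignment coefficients are modest
(0.20) and part of the observed dm-vs-non-dm stroke gap is carried by the
direct dm→y edge rather than by age confounding.  With stronger
treatment-by-indication for diabetics, the protective treatment pathway
would cancel the direct harm and the *total* causal effect of diabetes
would turn negative; the committed values keep the qualitative ordering of
total effects (af ≈ +0.074 > ht ≈ +0.022 > dm ≈ +0.004 > dlp ≈ 0) that the
analysis is designed to recover.

**Ground truth.** Treatment has no descendants other than the outcome, so
the per-patient potential-outcome probabilities are computed exactly from
the outcome equation at t = 1 and t = 0.  For risk-factor exposures, which
do have descendants, `ground_truth_effects()` runs a coupled two-world
Monte-Carlo: the exposure is forced to 1 and to 0 with shared structural
noise, descendants are re-propagated, and mean outcome probabilities are
contrasted (risk difference and ratio, with standard errors).

**Continuous latent outcome.** Alongside the binary stroke indicator the
generator emits `y_latent`: the factual outcome log-odds plus Gaussian noise
(sd 0.5 by default).  Quantile regression on a purely binary outcome yields
degenerate step-function quantiles, so coverage studies of the conformal
machinery use this continuous mode, where the true latent-scale ITE
(`mu1 - mu0`) is a known deterministic function of dm and ht.  Binary mode
remains the default for the end-to-end pipeline.

**What the generator does not emulate.** No time-to-event structure,
censoring or loss to follow-up; no coding noise in diagnoses; no unmeasured
confounding (every confounder is observable, so ignorability holds by
construction).  Passing recovery tests on these cohorts therefore
demonstrates statistical correctness of the estimators under the stated
assumptions, not robustness to the ways real hospital data violate them.

# Average-effect estimators

All estimators target the average risk difference and consume the same
cohort schema and DAG-derived adjustment sets.

* **Stratified propensity scores** (`sps_ate`): patients are binned on the
  fitted propensity by recursive bisection of the unit interval; a split is
  accepted only while every stratum keeps at least 10 exposed and 10
  unexposed patients, so the number of strata adapts to the data.  The ATE
  is the stratum-size-weighted mean of within-stratum outcome differences.
* **Inverse probability weighting** (`ipw_ate`): the Horvitz–Thompson
  contrast `mean(AY/e) - mean((1-A)Y/(1-e))`, with a normalized (Hájek)
  variant.  Propensities are clipped to [0.01, 0.99] — the clipping bound is
  a variance/bias dial surfaced in the interface, not hidden.
* **Doubly robust / augmented IPW** (`dre_ate`): arm-specific L1-penalized
  logistic outcome regressions (penalty by 5-fold cross-validation) plus
  the inverse-propensity correction.  Either nuisance can be supplied
  directly, which the test-suite uses to demonstrate — not merely assert —
  double robustness: the estimator stays consistent when the outcome model
  is replaced by an intercept or when the propensity is replaced by the
  marginal rate, while plain IPW fails the latter.
* **Logistic odds ratio** (`logistic_or_baseline`): the conventional
  epidemiological adjusted odds ratio with a Wald interval, kept as the
  bridge to standard cohort analyses.
* **Double machine learning** (`dml_ate`): K-fold cross-fitting (default 5)
  with the interactive AIPW-type orthogonal score.  The score choice is a
  design decision: for a binary treatment and a risk-difference estimand
  the interactive score is the natural Neyman-orthogonal moment; the
  partially-linear score would estimate a different functional.  The linear
  variant uses lasso outcome models and logistic propensity; the nonlinear
  variant gradient-boosted trees (depth 3, 200 rounds, learning rate 0.1)
  for both.  The "final stage" for a scalar ATE is the aggregation of the
  orthogonal scores: their mean, with the empirical influence-function
  standard error, reported as the median over 3 fold-assignment seeds to
  suppress partition randomness.

Confidence intervals for the classical estimators use the percentile
bootstrap over patients (B = 500 by default, seeded).  The reporting choice
of CI method is uniform across estimators so that interval widths are
comparable.

# Mediation

`mediation_effects()` implements the mediational g-formula for binary
mediators: natural direct and indirect effects with the mediator held at
its untreated-regime distribution,

NDE = E_Z Σ_m [E(Y|x=1,m,Z) − E(Y|x=0,m,Z)] P(m|x=0,Z),
NIE = E_Z Σ_m E(Y|x=1,m,Z) [P(m|x=1,Z) − P(m|x=0,Z)].

With these reference levels NDE + NIE equals the total effect *exactly*,
and the implementation preserves that identity to floating precision for
every fitted model — the test suite checks 1e-10.  Joint mediators (ckd and
af for hypertension; ht and ckd for diabetes) are handled through their
joint conditional distribution factorized in topological order, so each
mediator model conditions on the mediators upstream of it; this respects
structures like ckd ← ht → af and ht → ckd.  A `saturated` option fits all
exposure-mediator interactions, making the fitted models equal the
empirical conditional tables and the g-formula equal exhaustive
enumeration — the device the tests use for exact oracle comparisons.
Identification assumes no exposure-induced mediator-outcome confounding,
which holds in the default diagram.

# Dragonnet

`fit_dragonnet()` trains a three-headed network: a shared representation
φ(X) ∈ R^200 (three ELU layers), two outcome heads of two hidden layers
(width 100) each ending in a sigmoid — one per treatment arm — and a single
linear-plus-sigmoid propensity head reading directly off φ(X).  Each
observation contributes to the outcome loss only through its factual head;
the propensity cross-entropy (weight 1 by default) forces the
representation to retain confounder information, which is the point of the
architecture: a representation good enough to predict treatment is good
enough to deconfound the outcome heads.

Targeted regularization is on by default (strength 1): a trainable scalar
fluctuation ε perturbs the factual prediction along the inverse-propensity
"clever covariate" and the squared perturbation error joins the loss.  In
this implementation the regularizer's gradient treats the clipped
propensity as a fixed covariate (as in the targeted-learning view where the
fluctuation is fitted at a frozen nuisance); gradients flow through the
outcome heads and ε.

Training details, all seeded and exactly reproducible: continuous
covariates are z-scored with training-split statistics only; minibatch Adam
(batch 512, learning rate 1e-3); 20% validation split with early stopping
at patience 5; non-finite losses abort with diagnostics.  The forward and
backward passes are plain matrix algebra, so a fit is a deterministic
function of the seed.

From the fitted heads, `predict_potential_outcomes()` returns per-patient
(ŷ1, ŷ0, ê); `cate()` averages ŷ1 − ŷ0 within covariate strata;
`causal_risk_ratio()` forms mean(ŷ1)/mean(ŷ0) with a patient bootstrap.
`dragonnet_ate()` reports either the plug-in contrast or (default) the
AIPW-corrected estimate that combines the heads with the network's own
clipped propensity and the observed outcomes — the estimator the targeted
regularization is shaping the heads for, and the one with a valid
influence-function standard error.

# Conformal ITE intervals

The conformal module answers: for each untreated patient, what interval
contains their individual treatment effect with 95% probability?  The
construction is nested weighted split-conformal quantile regression.

**Stage 1 — counterfactual intervals.** The cohort is split evenly into a
training and an evaluation part (the even split is itself a protocol
choice).  Half the training part fits, per treatment arm, gradient-boosted
pinball-loss regressors of the outcome at quantile levels α/4 and 1 − α/4,
plus a logistic propensity model.  The other half calibrates conformity
scores `max(q_lo(x) − y, y − q_hi(x))`.  Because calibration patients of,
say, the treated arm are not distributed like the whole cohort (covariate
shift), the score quantile is weighted by the likelihood ratio — 1/e(x) for
arm 1, 1/(1−e(x)) for arm 0 — normalized per test point with the standard
point mass at infinity.  Each evaluation patient then gets an interval for
their *unobserved* arm, which combines with their observed factual outcome
into bounds [L, U] on their ITE.

**Stage 2 — the nested step.** The stage-1 bounds exist only for patients
with an observed outcome, and inherit that outcome's noise.  The nested
stage therefore regresses L and U on the covariates (one half of the
evaluation part) and conformalizes the two bound-regressors (other half) at
level 1 − α/2, yielding intervals `[l̂(x) − η₂, û(x) + η₂]` defined for
every covariate profile.

**Miscoverage budget.** The total α (default .05) is split evenly: stage 1
guarantees P(ITE ∈ [L, U]) ≥ 1 − α/2 for a fresh patient, stage 2
guarantees P([L, U] ⊆ final interval) ≥ 1 − α/2, and a union bound gives
marginal ITE coverage ≥ 1 − α.  Conformal methods over-cover in practice;
the acceptance study (200 cohorts of 2,000 patients, continuous latent
outcome) observes coverage near 100% at α = .05, comfortably above the
nominal floor, at the price of conservative widths.

**Numerical conventions.** The weighted score quantile follows the standard
convention: the smallest score whose cumulative normalized weight reaches
the level, with the test point's own weight on a point mass at +∞; when the
finite scores cannot carry the required mass the largest score is used as a
finite cap — a documented approximation to the infinite interval, relevant
only under extreme weights.  The uniform-weight rank convention reduces to
the usual ⌈(1−α)(m+1)⌉ order statistic.  Quantile boosting uses a larger
step size (0.3) and more rounds (300) than a squared-error fit would:
the pinball gradient at extreme quantiles is tiny on one side, and a timid
learner never reaches the conditional tail.  Bound crossings are repaired
by swapping; point estimates (the Dragonnet contrast when the pipeline
supplies it, otherwise the interval midpoint) are clamped into their
interval; binary-outcome intervals are clamped to [−1, 1].

**Stratified summary.** `stratified_ite_summary()` restricts to untreated
patients and summarizes point ITEs over the 2³ combinations of ht, dm, dlp
(mean, interquartile range, count).  Atrial fibrillation is deliberately
refused as a stratum — it is not an indication for antiplatelet therapy —
but remains a covariate everywhere.  On default synthetic cohorts the dm
and dm+ht strata show the most negative means, matching the generator's
construction.

# Pipeline and reproducibility

`run_full_analysis()` drives everything from one configuration: per
exposure it derives the adjustment set and runs the requested estimators
(failures are recorded in the JSON run manifest without aborting the other
stages), runs mediation for exposures with mediators, and runs the
Dragonnet + conformal ITE analysis for the antiplatelet treatment.  Outputs
are schema-validated CSVs plus a manifest carrying the seed, a hash of the
configuration echo, versions and per-stage errors.  A single global seed
propagates to every stochastic component; rerunning an identical
configuration is byte-identical.

# Validation design and problem sizes

The test suite validates every layer against an independent oracle:
d-separation against exhaustive path enumeration; backdoor sets against
brute-force subset search; generator ground truth against an uncoupled
re-implementation of the two-world simulation and against closed-form
numeric integration in single-edge models; estimators against hand-computed
toy tables (exact to 1e-10) and against the generator's truth at scale;
mediation against exhaustive enumeration on saturated tables (exact) and
against the decomposition identity (1e-10); the conformal core against its
analytic limiting cases and Monte-Carlo coverage.

The standing simulation sizes are: estimator-consistency checks at
n = 50,000 (confounded) and n = 20,000 (randomized); double-robustness
demonstrations at n = 30,000; conformal coverage over 200 cohorts of
n = 2,000; generator calibration at n = 100,000 (matching the precision of the
whole-percent target rates).  These sizes put Monte-Carlo error well below the
3-standard-error decision bands used throughout.

# Known limitations

* The conformal intervals are conservative (the even α split and the
  two-stage construction both cost width); sharper budgets exist when one
  is willing to trade finite-sample guarantees for asymptotics.
* Binary-outcome quantile surfaces are step functions; per-patient
  intervals in binary mode are coarse by nature, which is why coverage
  studies use the continuous latent outcome.
* The Dragonnet implementation is CPU-oriented and deliberately excludes
  GPU-scale training and hyperparameter search; the architecture defaults
  follow the original Dragonnet design (200-wide x3 representation,
  100-wide x2 heads, ELU).
* Mediation supports binary mediators only, and interventional (stochastic)
  direct/indirect effects are out of scope.
* All causal conclusions are conditional on the encoded diagram; the
  package does no structure learning.
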