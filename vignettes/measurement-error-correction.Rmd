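---
title: "Correcting self-report bias with a validation subsample: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting self-report bias with a validation subsample}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`surveymime` estimates the prevalence of overweight, obesity, hypertension
and hypercholesterolemia from health-interview self-reports, corrected for
measurement error using an examination validation subsample. This vignette
is the package's own account of the statistical machinery: the models and
their assumptions, the tunable parameters and why their defaults are what
they are, what the synthetic generator does and does not emulate, and the
numerical choices a user auditing results will want to know about.

## The measurement-error setting

Each respondent carries error-prone self-reports (height, weight, and
yes/no answers about hypertension and high cholesterol) and, for a random
subsample only, objective measurements (height, weight, blood pressure,
antihypertensive-medication use, total serum cholesterol). The indicator
definitions applied to measurements are fixed throughout:

* BMI = weight (kg) / height (m)²; overweight: BMI ≥ 25; obesity: BMI ≥ 30.
* Hypertension: systolic ≥ 140 mmHg, or diastolic **strictly** > 90 mmHg,
  or antihypertensive medication.
* Hypercholesterolemia: total cholesterol **strictly** > 190 mg/dl.
  Lipid-lowering medication is deliberately excluded from the definition,
  because statins are widely used preventively and their inclusion would
  reclassify treated-but-controlled respondents.

Because the validation subsample is drawn completely at random, respondents
with and without measurements are exchangeable: missingness of the measured
variables is MCAR by design, so MAR — the condition under which multiple
imputation yields valid inference — holds automatically. This is the single
most load-bearing assumption of the whole pipeline; with a self-selected
examination sample it would fail and nothing downstream would be
trustworthy.

## Step 1: agreement diagnostics

On the validation subsample the package quantifies agreement between
self-reported and measured values. Continuous variables get the
Bland–Altman analysis: the (survey-weighted) mean difference
self-minus-measured and the limits of agreement, defined as the mean
difference ± 1.96 × SD of the differences. The weighted SD uses the
frequency-consistent form `sum(w (d - m)^2) / (sum(w) - sum(w^2)/sum(w))`,
which reduces to the n−1 sample variance under equal weights and is
invariant to rescaling all weights; confidence intervals use the paired-*t*
machinery with the effective sample size `(Σw)²/Σw²`. The 1.96 multiplier
is used literally (not `qnorm(0.975)`), matching the convention of the
agreement literature.

The ICC is the two-way absolute-agreement single-measure form, computed
from the subject × rater ANOVA decomposition with the F-based confidence
interval. *Absolute agreement* rather than *consistency* is a deliberate
choice: a systematic reporting bias should lower the coefficient, not be
absorbed into a rater effect.

Binary indicators get the weighted confusion matrix (sensitivity,
specificity, PPV, NPV, with empty margins reported as `NA`, never 0),
unweighted Cohen's kappa (categories treated as nominal, including the
BMI-category comparison), and McNemar's `(b − c)²/(b + c)` on the
**unweighted** discordant counts — the weighted exact distribution of the
McNemar statistic is not well defined, so weights enter the descriptive
proportions but not the paired test.

## Regression calibration

For each outcome a model predicts the measured value from the self-report
plus age, sex and education (household's highest level, four ordered
categories coded as dummy variables): linear regression for height and
weight, logistic for the binary conditions. Candidate self-report ×
covariate interactions are screened **forward, one at a time, in the fixed
order age, sex, education**, each kept when its joint Wald test (all added
coefficients) is significant at 5%; the fixed order makes the procedure
deterministic. Predictive accuracy is the held-out R² or AUC from a 70/30
split, stratified on the outcome for binary conditions so small validation
samples cannot produce single-class test sets; held-out rows with factor
levels unseen in the training split are excluded from scoring. After the
accuracy check the selected model is refitted on the full validation sample
for substitution (disable with `refit_full = FALSE`); refitting uses all
the information the validation sample offers, at the cost of the accuracy
metric describing a slightly smaller model.

Substitution replaces continuous self-reports by predicted means and binary
self-reports by predicted probabilities; corrected BMI is recomputed from
the predicted height and weight, and the overweight/obesity flags from the
corrected BMI. The calibrated prevalence of a binary condition is the
weighted mean predicted probability — averaging probabilities avoids an
arbitrary 0.5 classification cut-off the substitution recipe never
specifies.

Calibration's known limitation is inherited deliberately: the prevalence
estimates and their confidence intervals treat the predictions as fixed,
ignoring calibration-model uncertainty. For the **standard-error-ratio
diagnostic only**, the calibrated SE adds a model-uncertainty component by
redrawing model coefficients from their estimated sampling distribution
(default 100 draws) and adding the across-draw variance of the weighted
prevalence to the design variance. Without this component the ratio
diagnostic would be meaningless for calibration — the design variance of
near-constant predicted probabilities is tiny regardless of how poor the
model is — whereas with it a weakly predictive model (e.g.
hypercholesterolemia, AUC ≈ 0.6) is properly penalized and multiple
imputation dominates, while strongly predictive models keep ratios above 1.

## The chained-equations engine

The measured height, weight, hypertension and hypercholesterolemia of
non-examined respondents are imputed `m` times by chained equations.
Covariates with item nonresponse are imputed in the same sweeps.

**Predictor sets.** Each variable's default model conditions on the
self-report of the same condition, age, sex, education, household size and
province (wave year too when several waves are present) — **and on the
other measured variables**. Conditioning on all other variables is the
chained-equations principle; omitting the cross-measured predictors breaks
the conditional height–weight correlation and demonstrably inflates the
variance of imputed BMI (≈ +1.5 prevalence points on obesity in our
simulations). A wider sensitivity-analysis predictor set, or a multi-wave
model with wave year, is configured through `imputation_spec(predictors =
...)` rather than a separate code path.

**Imputers.**

* *Predictive mean matching* (continuous): coefficients are drawn from the
  approximate posterior of a Bayesian linear regression (σ² from a scaled
  inverse-χ² draw, coefficients from the corresponding normal, with a
  10⁻⁵-scaled ridge to tolerate near-singular designs); predicted means use
  the posterior mean for observed rows and the drawn coefficients for
  missing rows; each missing row then draws uniformly among its `pmm_donors
  = 5` closest observed rows by predicted mean (the conventional donor
  count), with ties broken by sort position. Imputed values are therefore
  always observed values — no impossible heights or BMIs.
* *Logistic* (binary): a posterior-mode fit with a weakly informative
  normal prior (SD 2.5 per standardized coefficient, 10 on the intercept)
  and a Gaussian posterior draw. The prior leaves ordinary fits essentially
  untouched but keeps draws proper under quasi-separation. Under
  **complete** separation (a perfectly informative self-report) the
  Gaussian approximation itself fails — draws of many weakly identified
  coefficients push probabilities toward ½ — so when the fitted model
  classifies the observed data essentially perfectly the imputer switches
  to donor matching on the fitted score, which reproduces the
  deterministic mapping. Single-class outcomes fall back to shrunken
  prevalence draws with a warning.
* *Categorical covariates*: predictive mean matching on a score scale
  (Bayesian linear regression on the integer level codes, donor draw of an
  observed level).
* *Random forest*: `n_trees` trees (ranger), one tree chosen at random per
  missing row, imputation by a uniform draw among the observed outcomes in
  that row's terminal node (regression trees, minimum node size 5, for
  continuous outcomes; classification trees, minimum node size 1, for
  binary). The donor draw — rather than averaging tree predictions —
  preserves imputation variability. On top of the tree mechanism the
  engine resamples the whole donor pool with replacement (an approximate
  Bayesian bootstrap) before growing the forest, redrawn at every update:
  without this layer, forest imputations share almost no parameter
  uncertainty across a chain's missing rows, Rubin's between-imputation
  variance collapses to roughly a third of its proper size, and pooled
  intervals undercover badly. With the pool itself resampled, the trees
  are grown on that resample directly (diversity coming from `mtry` and
  split randomization); standalone calls with `abb = FALSE` recover plain
  bagging.

**Scheduling.** Chains are initialized by random draws from each
variable's observed values and swept `n_iterations` times through the
visit sequence, ordered by ascending missingness (least missing first), so
nearly complete covariates stabilize before the mostly missing measured
variables. BMI, overweight and obesity are derived passively from the
completed height and weight after every sweep and are never imputed
directly — every completed copy satisfies the threshold definitions
exactly. Observed cells are never overwritten. Each chain runs on an
independent RNG sub-stream derived from the master seed, so a run is
reproducible bit for bit and chains are exchangeable.

**Defaults.** `m = 10` completed datasets (relative efficiency above 99%
for moderate fractions of missing information), `n_iterations = 100`,
`n_trees = 100` — a production-scale operating point for public-use
completed datasets. The package's own
simulation studies use the reduced profile (`reduced_profile()`: n = 2,000
respondents, 300 examined, m = 5, 10 iterations, 20 trees), chosen so a
full recovery study of 50 replicates runs in minutes while leaving the
qualitative behaviour unchanged.

**Convergence.** The engine logs the mean and SD of the imputed values per
chain × iteration × variable. `convergence_summary()` compares, over the
final `window` iterations, the between-chain variance of the chain-level
mean to the within-chain iteration-to-iteration variance; the ratio
`B/(W/window)` is ≈ 1 for stationary well-mixed chains and is flagged above
a threshold of 5 — roughly the 99.8th percentile of the stationary
distribution with five chains, so well-specified runs are flagged less
than 1% of the time while a shifted chain is flagged immediately.
`autoplot()` renders the standard trace plots.

## Survey-weighted estimation and pooling

Prevalence is the ratio estimator Σwᵢyᵢ/Σwᵢ with Taylor-linearized variance
under with-replacement sampling of clusters within strata. A stratum left
with a single cluster is merged into the adjacent stratum with a warning
(or raises an error under `single_cluster = "error"`); if the design
degenerates to one cluster in total, respondents are treated as independent
PSUs, recovering the simple-random-sampling form p(1−p)/(n−1) under equal
weights.

Per-imputation estimates are combined by Rubin's rules with the
Barnard–Rubin small-sample degrees of freedom, taking the design-based
clusters-minus-strata as the complete-data degrees of freedom. Confidence
intervals are symmetric on the proportion scale, the convention of
prevalence tables in this field; a logit-scale option was considered and
rejected as a default for that reason. The fraction of missing information γ and the relative
efficiency (1 + γ/m)⁻¹ are reported with every pooled estimate. The
SE-ratio table divides the validation-subsample-only design SE by each
method's adjusted full-sample SE: ratios above 1 mean the correction
delivers more precision than simply analysing the examined subsample.

## What the generator emulates — and what it does not

`simulate_bhis()` draws demographics (age 18–90 with a broad mode near 50,
sex, four education levels, eleven province labels, household size), then
truth: height normal within sex (177.5/164.5 cm means, SD 7, mild decline
with age), weight linear in height (0.8 kg/cm, residual SD 14 around 74.5
kg at 170 cm — overweight ≈ 55%, obesity ≈ 19%), hypertension and
hypercholesterolemia Bernoulli with marginal prevalences 0.33 and 0.47 and
a linear age gradient (0.006/year, centred so the marginal is exact), and
continuous blood pressure / medication / cholesterol values drawn from
mixtures **exactly consistent** with the binary truth under the indicator
thresholds, so the threshold logic is exercised end to end.

Self-report error: `sr = centre + slope·(true − centre) + bias + noise`
with a global attenuation slope 0.92 (the "flat slope syndrome"),
subgroup-specific biases (height +1.05 cm on average, more for women, the
elderly and the low-educated; weight −1.50 kg, slightly more for women and
the highly educated) and reporting noise (SD 2.8 cm / 4.0 kg), calibrated
as loose emulations of the published stratified bias tables so that
self-reported BMI is under-reported by ≈ −0.9 kg/m². Binary self-reports
are misclassified truth at sensitivity/specificity 45/99
(hypertension) and 22/83 (hypercholesterolemia); the joint distribution of
reporting errors across variables is independent given the truth, which is
an assumption of convenience, not an estimate. The design layer groups
provinces into strata, nests random clusters within strata, and assigns
weights varying by province and household size; it makes no attempt to
mimic any real weighting algorithm, and cluster labels carry no
within-cluster outcome correlation. Passing tests therefore demonstrate
that the estimators are correct under a faithful, MCAR-validated,
moderately heterogeneous error structure — not that any particular
real-world survey satisfies those conditions.

## Numerical choices and degenerate inputs

* Ridge 10⁻⁵ (scaled by the diagonal) in the Bayesian linear draw;
  exact rank deficiency still raises an error naming the collinear columns.
* Logistic prior SD 2.5 per standardized coefficient; complete-separation
  fallback to score matching as described above.
* PMM donor search restricted to the 2k-wide sorted window that provably
  contains the k nearest donors; ties broken by sort position.
* Zero-variance predictor columns (empty factor levels among observed
  rows) are dropped per update.
* Degenerate requests fail loudly: prevalences outside [0, 1], non-positive
  SDs or weights, validation fractions outside (0, 1), m < 2, fully missing
  variables, unknown predictors, windows longer than the chain.
* Undefined quantities propagate as `NA` ("undefined"), never as 0: empty
  confusion margins, AUC on single-class test sets, SE ratios with a zero
  denominator.

## Known limitations

* Calibration CIs ignore prediction uncertainty by design (reported, not
  fixed); use the imputation engines when interval validity matters.
* The RF imputer's between-imputation variance, even with the bootstrap
  layer, reaches only ~90% of its theoretically proper spread for nearly
  uninformative predictors; with m = 5 and a fraction of missing
  information near 0.85, ±2·SE recovery checks sit at their theoretical
  edge (coverage of a fixed 2-SE box is capped near 0.90 by the t-tails at
  4 between-imputation degrees of freedom).
* McNemar is the asymptotic χ² form; no exact or mid-p variant.
* Kappa is unweighted; ordered BMI categories are treated as nominal.
* No replication-weight (jackknife/BRR) variance estimation and no weight
  construction — weights, strata and clusters are taken as given.
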