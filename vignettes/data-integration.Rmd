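---
title: "Correcting selection bias in convenience health surveys by data integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting selection bias in convenience health surveys by data integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Convenience (non-probability) health surveys — web panels, community
recruitment, volunteer registries — have no known inclusion mechanism.
When who responds depends on who they are, raw estimates are
selection-biased: a sample that over-represents older, female, lower-income,
higher-BMI respondents will overstate the prevalence of arthritis and
diabetes no matter how large it is. surveyfuse implements two data
integration remedies that borrow strength from a probability-sample
reference survey sharing a set of demographic/health covariates:

1. **Calibration weighting** — reweight the convenience sample so its
   weighted covariate margins match the reference survey's design-weighted
   margins; and
2. **Sequential mass imputation** — fit outcome models on the convenience
   sample (where the outcomes are observed) and impute the outcomes into the
   reference sample, then estimate with the reference sample's design
   weights.

Both are evaluated against known truth on a synthetic finite population, so
every estimator's bias is measurable without restricted survey data.

## Models and procedures

### Composite weighting of stacked reference waves

Two (or more) waves of the reference survey are stacked; every record's
design weight is divided by the number of waves $W$, so the pooled weighted
total estimates the population size once rather than $W$ times. The wave
label and the original stratum are concatenated into a new stratification
variable, so variance strata never mix waves. `composite_combine()` performs
this and records `.composite_weight` and `.stratum`.

### Calibration

With initial weights $w_i$ (unit weights for a convenience sample) the
calibrated weights $\tilde w_i$ minimize the chi-square distance

$$\sum_{i \in s_B} \tfrac12 \left( \tilde w_i / w_i - 1 \right)^2
\quad \text{s.t.} \quad
\sum_{i \in s_B} \tilde w_i x_i = \sum_{i \in s_A} d_i x_i,$$

where $x_i$ stacks category indicators of the calibration covariates and
$d_i$ are the reference design weights. Two solvers are exposed, because the
quadratic distance and the iterative proportional fitting algorithm commonly
used to compute calibration weights are *not* the same estimator:

* `calibrate_linear()` returns the exact stationary solution
  $\tilde w_i = w_i + w_i^2 \lambda^\top x_i$ with
  $(\sum w_i^2 x_i x_i^\top)\lambda = T - \sum w_i x_i$, on a non-redundant
  (`reference_dropped`) constraint system. It is the literal optimum of the
  distance above, verified in the test suite against a generic
  equality-constrained quadratic minimizer (a KKT block solve). Quadratic
  calibration can produce negative weights; the default policy falls back to
  raking with a warning, because negative weights break frequency
  estimation downstream.
* `calibrate_raking()` cycles over the covariates, scaling each category
  cell by (benchmark total / current weighted total) until every margin
  matches within `tol` (default $10^{-8}$ relative, `max_iter` 1000).
  Raking keeps weights strictly positive and is the default in the pipeline,
  mirroring how calibration weights are usually computed in practice. At
  these margins (2-decimal reporting) the tight default tolerance costs a
  few milliseconds.

Both methods yield identical calibrated *margins* when a single variable is
calibrated (a tested invariant); their weights differ in general.

### Sequential mass imputation by fully conditional specification

For each outcome, a prediction model is fitted on the convenience sample:
logistic regression for binary outcomes, multinomial for categorical
outcomes with more than two levels, linear for continuous ones. The
predictor set is the main effects of the categorical covariates plus, by
default, all two-way interaction terms. Outcomes are then imputed into the
(combined) reference sample one at a time, once — a single imputed file, no
multiple imputation. `draw_mode = "stochastic"` draws Bernoulli/normal
values from the fitted predictive distribution; `"expected"` stores the
predicted probability or mean for plug-in estimation.

"Sequential by FCS" is read here as: each outcome's model conditions on the
covariates (and interactions) only, since that is the canonical predictor
set for this problem. Whether later outcomes should also condition on
earlier *imputed* outcomes is genuinely ambiguous; `chained = TRUE` enables
that reading, off by default, and the provenance attribute records which
was used. The default imputation order is the order the outcomes are
listed; it is configurable and recorded.

Item missingness is handled *before* integration by
`fcs_single_impute()`: variables are visited in ascending missing-rate
order, each modeled on all other listed variables with the currently
completed data, and missing entries replaced by draws from the fitted
predictive distribution (hot-deck fallback if a model fails, logged).
Observed values are never altered. Single imputation is appropriate at the
low item-missing rates (a few percent) this workflow targets.

### Estimation and testing

`weighted_frequency()` produces weighted frequencies and percents.
`rao_scott_test()` compares a categorical distribution between two weighted
samples: the Pearson homogeneity statistic on the design-weighted
proportions is divided by a first-order design-effect correction, the mean
over samples and levels of
$\widehat{V}_{\text{Taylor}}(\hat p) / \big(\hat p(1-\hat p)/(n-1)\big)$,
with stratified with-replacement Taylor-linearization variances. The
$(n-1)$ denominator convention makes the equal-weight single-stratum case
reduce *exactly* to Pearson's chi-square; the first-order correction keeps
$K-1$ degrees of freedom. The second-order (Satterthwaite) variant is out
of scope. Strata with a single record contribute zero variance with a
warning (certainty-unit convention), so small synthetic strata never crash
the pipeline. `weighted_mean_compare()` is the continuous analogue: the
difference of weighted means with combined linearized variances, equivalent
to a survey-weighted regression on a sample indicator.

## Numerical choices

* **Ridge-stabilized fits.** Two-way interactions among eight categorical
  covariates at $n \approx 635$ give ~175 predictor columns and
  separation-prone logistic likelihoods. All logistic/linear fits use a
  small ridge penalty (default $10^{-4}$) on standardized predictors with
  an *unpenalized intercept*, solved by damped Newton (step-halving on the
  penalized deviance, convergence at $10^{-10}$ step size). The unpenalized
  intercept preserves the score equation $\sum_i (y_i - \hat p_i) = 0$
  exactly, so expected-mode self-imputation reproduces the fitting sample's
  prevalence to machine precision — a tested invariant.
* **Column retention.** Predictor columns with zero variance in the fitting
  sample are dropped first, then exactly collinear columns via pivoted QR;
  both lists are recorded in the model object. A recipient record that
  activates a dropped zero-variance column (a covariate level unseen during
  fitting) is mapped to the reference level with a warning, or rejected
  under `unseen_policy = "error"`.
* **Raking degeneracies.** A benchmark cell with positive total but no
  sample records is infeasible and reported by name; an occupied cell with
  a zero benchmark would force weights to zero and is likewise an error
  (raking weights stay strictly positive). Non-convergence at `max_iter`
  returns a result flagged `converged = FALSE` with diagnostics, never a
  silent success.
* **Determinism.** Every stochastic step takes an integer seed and runs
  under an isolated RNG scope; identical inputs and seed give bit-identical
  populations, samples, imputations and reports. The pipeline stores a hash
  of its inputs and options in the result's metadata.

## The synthetic harness

`population_config()` describes a finite population; its defaults mirror
the motivating study's scale: $N = 300{,}000$ adults, eight categorical
covariates (age group, gender, marital status, education, employment,
income, BMI category, general health), nine binary outcomes (smoking,
arthritis, CVD, COPD, asthma, cancer, stroke, diabetes, health coverage), a
two-wave stratified reference survey totalling ~973 records with design
weights $N_h/n_h$, and a convenience sample of ~635 expected records whose
inclusion propensity depends on the covariates. The default selection
coefficients produce the skew convenience health surveys show — roughly 78%
female against ~51% in the population, plus over-representation of older,
lower-income, higher-BMI, poorer-health respondents. Covariates are
correlated through an exchangeable latent Gaussian copula (correlation 0.3)
so that calibrating on covariates meaningfully transfers to outcomes;
outcome models are main-effects logistic with epidemiologically plausible
coefficient signs and magnitudes (0.3–1.6 on the logit scale), designed so
every outcome's selection-induced naive bias is material (≥ ~1.3 percentage
points) and single-signed. Item missingness defaults to 2% MCAR on two
covariates, exercising the pre-integration imputation stage at the low
rates the workflow targets.

Truth is computed by enumerating the realized population, never from the
generating parameters, so Monte-Carlo bias estimates are exact up to
sampling noise.

What the generator does *not* emulate: dual-frame telephone sampling
mechanics, nonresponse follow-up, post-stratification raking cells,
measurement error, or informative missingness. Passing tests therefore
demonstrate correct behaviour under covariate-driven selection with
correctly specified outcome models — the regime where these methods are
theoretically justified — not robustness to the many ways real surveys
violate those assumptions.

## The bias study and its model choice

`run_bias_study()` fixes one population, then repeatedly draws the two
reference waves and the convenience sample, runs the full pipeline, and
summarises each method's bias against the enumerated truth. The default
uses 50 replicates; the test suite runs exactly that size, which keeps the
whole study around a minute on one core while the Monte-Carlo standard
errors (~0.2–0.6 percentage points) remain small relative to the naive
biases (~1.3–6.6 points).

One deliberate choice: the bias study fits the imputation models with main
effects only (`interactions = FALSE`), while the pipeline default for real
data keeps the full interaction set. The synthetic outcomes are generated
from main-effects logistic models, so main effects *are* the correctly
specified model; the ~175-column interaction set at $n \approx 635$
overfits, and the convexity of the inverse-logit at small probabilities
turns that prediction noise into a systematic upward bias of several
percentage points for rare outcomes. That is a finite-sample
overparameterization artifact, not a property of mass imputation, and the
study isolates the estimator's behaviour under its stated assumptions.

## Known limitations

* No variance estimates or confidence intervals for the calibrated and
  mass-imputation estimators (point-estimate bias is the evaluation
  target); no replicate-weight methods.
* No propensity-score weighting for the convenience sample, and no bounded
  (logit) calibration distance.
* Calibration transfers to an outcome only through its association with the
  calibrated covariate margins; outcomes driven by unmeasured selection
  remain biased, and nothing in the package can detect that.
* The Rao-Scott correction is first-order only, and equivalence with any
  particular commercial implementation's variance estimator is not claimed.
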