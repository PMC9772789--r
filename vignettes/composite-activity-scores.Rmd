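---
title: "Deriving composite physical-activity scores that predict mortality"
author: "actisurv authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving composite physical-activity scores that predict mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actisurv)
```

## The problem

Wrist accelerometry yields, after upstream preprocessing (calibration,
non-wear detection, sleep detection), a sequence of 60-second epochs per
participant, each carrying an average acceleration in milligravity (mg,
ENMO metric) and a waking-period flag. From these epochs a rich family of
movement-behaviour features can be computed — how much time is spent
sedentary, how that time is accumulated into bouts, how intense activity
is, and when it happens. These features are strongly inter-correlated, so
entering them jointly into a mortality model is unstable, and picking one
at a time wastes information. The approach implemented here derives a small
number of *composite scores* — sparse linear combinations of the features —
tuned to predict all-cause mortality under censoring, and then quantifies
what those scores add to a survival model that already contains traditional
risk factors.

`actisurv` implements the full chain as a reusable, tested pipeline:

1. **`simulateEpochSeries()` / `simulateFeatureCohort()` /
   `simulateSurvival()`** — a synthetic-cohort generator with known ground
   truth (the real cohorts this design emulates are access-restricted);
2. **`extractFeatures()`** — 21 features spanning six behavioural
   dimensions;
3. **`fitSplsCox()` / `tuneSplsCox()`** — sparse partial least squares
   against deviance residuals of the censored outcome;
4. **`fitCoxModel()` and the evaluation suite** — hazard ratios per SD,
   Royston's $R^2_D$, AIC, Harrell's C, Youden sensitivity/specificity,
   bootstrap nested-model comparison, spline nonlinearity tests, subgroup
   and external validation;
5. **`runPipeline()`** — the orchestrated end-to-end run.

## Epoch classification and the 21 features

Waking epochs are classified by acceleration: below 40 mg is sedentary
behaviour (SB), 40–99 mg light-intensity physical activity (LIPA), and
100 mg or above moderate-to-vigorous activity (MVPA). The boundary
semantics are half-open: SB $[0, 40)$, LIPA $[40, 100)$, MVPA
$[100, \infty)$. A *bout* is a maximal uninterrupted run of same-state
epochs; no interruption tolerance is applied, and a day boundary always
ends a bout.

The 21 features (`featureNames21()`) cover:

* **Overall level** — mean acceleration over waking epochs (mg).
* **Total duration** — min/day in SB, LIPA, MVPA.
* **Bout duration** — mean bout length per state (ratio of total state
  time to total bout count, so `mean_bout * n_bouts = duration` holds
  exactly); SB time split into bouts of $[0,10)$, $[10,30)$ and
  $[30,\infty)$ minutes; LIPA and MVPA time split at 10 minutes.
* **Frequency** — bouts/day per state and the count of days with at least
  30 min of MVPA.
* **Intensity distribution** — intercept and gradient of the OLS fit of
  $\ln(\text{minutes per day in bin})$ on $\ln(\text{bin midpoint})$ over
  non-empty fixed-width intensity bins. We use 25-mg bins from 0, natural
  logarithms, and drop empty bins; 25 mg is the dominant convention in the
  intensity-distribution literature and the method is otherwise
  binning-agnostic. A more negative gradient means activity time drops off
  faster with intensity.
* **Timing** — the clock-hour start of the most active 5 consecutive hours
  (maximal 300-epoch rolling sum of acceleration; earliest window wins
  ties, giving a deterministic, order-independent result).

Per-day quantities are averaged over retained days with equal weight.
Exact identities are enforced and tested: state durations tile the waking
period to the epoch, bout-category times add up to state totals, and
features are invariant to the order of identical days. An optional
rescaling (`standardizeByWaking()`) maps duration and count features to a
common reference waking duration, as a sensitivity analysis for
between-person differences in time awake; intensity, timing, mean-bout and
day-count features are left untouched so all identities survive rescaling.

## Sparse PLS for a censored outcome

A censored outcome cannot be regressed on directly, so the derivation uses
residuals of the null survival model as a working response. With
$\hat\Lambda_0$ the Nelson–Aalen cumulative hazard of the covariate-free
model, the martingale residual is $m_i = \delta_i - \hat\Lambda_0(t_i)$
and the deviance residual its symmetrised transform
$$d_i = \mathrm{sign}(m_i)\sqrt{-2\,[m_i + \delta_i
\log(\delta_i - m_i)]},$$
with the $\delta_i\log(\cdot)$ term taken as zero for censored
participants. Deviance residuals are preferred over raw martingale
residuals because their distribution is far less skewed, which stabilises
the covariance directions the PLS extracts.

With $X$ the column-standardised feature matrix, each component
$k = 1,\dots,K$ is built as

$$w_k \propto g_\eta(X_k^\top d_k), \qquad t_k = X_k w_k,$$

where $g_\eta(v) = \mathrm{sign}(v)\,\max(0, |v| - \eta \max_j |v_j|)$ is
the soft-thresholding operator with sparsity fraction $\eta \in [0,1)$,
$w_k$ is normalised to unit length, and both $X$ and $d$ are deflated by
regression on $t_k$ before the next component. Deflating $X$ makes the
in-sample scores exactly orthogonal, matching the two-score structure the
method is meant to produce; the support of $w_k$ is the selected feature
set of component $k$. Scores are standardised to SD 1 in the derivation
cohort so downstream Cox hazard ratios read *per SD increment*. For
transfer to new data the model stores the rotation
$W(P^\top W)^{-1}$, which reproduces the in-sample scores exactly and maps
any standardised feature table to scores in one multiplication.

$(K, \eta)$ are tuned by event-stratified $k$-fold cross-validation
(default 5 folds). The criterion is the average validation-fold Harrell C
of the linear predictor formed by a Cox model of the training-fold scores.
Harrell's C was chosen as the criterion because discrimination is the
quantity the downstream evaluation reports; ties in the CV criterion are
resolved towards the sparser (larger $\eta$), then smaller-$K$ cell.
Grid cells in which some component selects no feature are recorded as `NA`
in the trace and skipped. Both weight vectors and X-loadings are exported,
since "loadings" is used ambiguously in this literature.

Score transfer (`applyScore()`) supports two standardisation modes:
`"derivation"` re-uses the derivation cohort's feature means/SDs and score
constants; `"local"` recomputes them on the target cohort. Local is the
default for external validation because device placement and wear
protocol shift feature scales between cohorts; local standardisation makes
the score invariant to affine changes of the feature scales.

## Survival evaluation

Cox models are fitted by partial likelihood via the survival package with
Efron tie handling by default (year-resolution follow-up times produce
ties, and Efron is the lower-bias standard choice). The evaluation suite
reports, for a reference model of traditional risk factors (Model 1), the
model adding composite score 1 (Model 2) and optionally score 2 (Model 3):

* **HR per SD** with Wald 95% CI (inputs are required to be standardised —
  the function refuses a feature whose SD is not 1);
* **Harrell's C**: share of concordant comparable pairs ($t_i < t_j$,
  $\delta_i = 1$), tied predictors counting one half;
* **Royston's $R^2_D$**: the predictor is replaced by rankit scores scaled
  by $\kappa = \sqrt{8/\pi}$, the Cox coefficient of that regressor is the
  separation statistic $D$, and
  $R^2_D = (D^2/\kappa^2)/(\pi^2/6 + D^2/\kappa^2)$;
* **Youden-optimal sensitivity/specificity**: the positive label is any
  observed death during follow-up (censoring time is deliberately ignored —
  a documented simplification rather than a censoring-adjusted ROC), all
  midpoints between sorted unique risk values are scanned, and the
  earliest maximiser wins;
* **Nested-model comparison**: point $\Delta$AIC and $\Delta$C come from
  the full-sample fits; percentile 95% CIs from participant-level
  bootstrap resampling (1000 replicates by default) with both models
  refitted per replicate; a difference is "significant" when its CI
  excludes zero. Failed replicates are redrawn; more than 10% failures
  aborts.
* **Nonlinearity**: a likelihood-ratio test comparing the linear score
  term against linear plus the nonlinear restricted-cubic-spline
  component (3 knots at the 10th/50th/90th percentiles, hence one added
  basis column and one LRT degree of freedom).

Subgroup analysis reruns the Model-1-vs-Model-2 machinery inside strata
(e.g. age bands, sex), restandardising the score within each stratum.
External validation applies a stored score model to an independent cohort
and recomputes the full panel there.

## The synthetic-data generator

Two generators provide ground truth at different levels.

**Epoch level** (`simulateEpochSeries()`): an alternating-state
semi-Markov process. States follow a transition matrix with zero diagonal;
bout durations are geometric on epochs by default (memoryless — the
simplest law consistent with observed mean bout durations) with a
lognormal option; each epoch draws an intensity from a Beta distribution
rescaled onto its state's intensity support, so thresholding recovers the
generating state of every epoch exactly. The default "older-adult" profile
was chosen once to land on published cohort scales: roughly three quarters
of a 960-minute waking day sedentary (mean SB bout 10.5 min), short light
bouts, a small MVPA fraction, 9 recorded days, and a cohort mean
acceleration near 32 mg with intensity gradient near −2.1.

**Participant level** (`simulateFeatureCohort()`): features are drawn from
a Gaussian copula with normal marginals so that means/SDs and correlation
can be set independently. The default correlation is a single-factor
structure (pairwise $|r| \approx 0.42$, with activity timing uncorrelated
with everything else, mirroring the reported pattern) and the default
marginal moments are the published cohort means/SDs. Mortality follows a
proportional-hazards model: event times are drawn by inverting the
cumulative hazard $\Lambda(t) = \lambda_0 t^{\gamma} e^{lp}$ (exponential
by default, Weibull optional), censored at an administrative horizon of 8
years plus an optional exponential random-censoring process. The default
baseline rate (0.0073/year) was set so that the marginal event fraction is
about 10% at the 8-year horizon under the default coefficient structure
(five active features at per-SD log-hazard 0.26, plus age and sex
effects), mirroring the roughly 10% mortality of the emulated cohort. All
randomness flows from a single cohort seed; stage seeds in the pipeline
are fixed offsets of the top-level seed.

**What the generator does not emulate.** The epoch generator has no
diurnal structure (so the timing feature is uninformative noise around
mid-waking), no between-participant heterogeneity in the behaviour profile
(cohort SDs of epoch-derived features are much smaller than published
between-person SDs; the feature-level generator supplies realistic
between-person variance instead), no day-to-day autocorrelation, and no
non-wear or sleep-detection errors (those steps are upstream of this
package's scope). Passing tests therefore demonstrate correctness of the
algorithms and calibration of the inference under a proportional-hazards
world, not that real accelerometer data meet those assumptions.

## Numerical choices and degenerate inputs

* Epoch classification errors on negative accelerations, naming the epoch.
* The intensity fit requires at least two non-empty bins; fewer is an
  error, not a silent zero.
* M5 timing requires at least 300 waking epochs on some day; ties broken
  towards the earliest window.
* A state with no bouts has `mean_bout = 0` by convention, keeping the
  `mean_bout * n_bouts = duration` identity.
* `softThreshold()` may return an all-zero vector; the component fitter
  turns that into a typed `emptySelectionError` carrying the component
  index and $\eta$, which the tuner catches and records as `NA`.
* A numerically exhausted deflated feature matrix (covariance below
  $\sqrt{\epsilon}\,n$) also signals empty selection rather than returning
  noise directions.
* Constant covariates in a Cox design leave the partial likelihood flat:
  they get coefficient 0, an `NA` standard error, and still pay their AIC
  penalty. Rank-deficient non-constant designs are errors.
* A constant predictor yields $R^2_D = 0$ with a warning; a constant risk
  score has no Youden cutoff and errors.
* Cox convergence failure (50 Newton–Raphson iterations) and separation
  (|coefficient| > 15) are errors; inside the bootstrap they trigger a
  replicate redraw instead.

## Problem sizes used in tests and the demo

The packaged demo (`pipelineConfig()` defaults) simulates 500 participants
over 3 recorded days, tunes over $\eta \in \{0, 0.1, \dots, 0.9\}$ and
$K \in \{1, 2\}$ with 5 folds, uses 200 bootstrap replicates, and
externally validates on 300 independently simulated participants. The test
suite's recovery study uses 100 replicates of $n = 2000$ cohorts with 21
features at pairwise correlation 0.4, five active features at per-SD
log-hazard 0.26 and roughly 30% censoring (baseline rate 0.15 over an
8-year horizon); coverage checks use 500 replicates at $n = 4000$ with 10%
events. These sizes were chosen as the smallest at which the Monte-Carlo
bands in the assertions are comfortably narrower than the effects being
checked.

## A short worked example

```{r example, eval = FALSE}
spec <- cohortSpec(n = 1000, seed = 7)
cohort <- addSimulatedSurvival(simulateFeatureCohort(spec), spec)
pd <- participantData(cohort)

model <- tuneSplsCox(featureMatrix(cohort), pd$time_years, pd$event,
                     seed = 7)
model

pd$score1 <- as.numeric(scale(applyScore(model, featureMatrix(cohort),
                                         "derivation")[, 1]))
fit2 <- fitCoxModel(pd, c("age", "sex", "score1"))
hazardRatioPerSD(fit2, "score1")
performancePanel(fit2)
compareNestedModels(pd, c("age", "sex"), c("age", "sex", "score1"),
                    B = 200, seed = 7)
```

## Known limitations

* The Youden convention ignores censoring when labelling outcomes; with
  heavy early censoring the sensitivity/specificity are optimistic.
* $R^2_D$ is one member of the family of explained-variation measures for
  survival models; the implemented variant is stated exactly above rather
  than claimed equivalent to any other software's "Royston R²".
* The sparse PLS variant implemented (soft-thresholded covariance with
  double deflation on deviance residuals of the null model) is stated
  explicitly; other sparse-PLS-for-survival formulations exist and can
  give different supports at equal predictive performance.
* Bout detection applies no interruption tolerance; features based on
  tolerant bout definitions are not comparable.
* Proportional hazards is assumed throughout; competing risks and
  time-varying effects are out of scope.
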