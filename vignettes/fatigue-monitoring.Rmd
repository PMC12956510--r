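---
title: "Monitoring training load and predicting fatigue: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring training load and predicting fatigue: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fatiguelab)
library(dplyr)
```

`fatiguelab` implements the analysis pipeline of a multi-sensor
athlete-monitoring study: load indicators from GPS/accelerometer and
heart-rate data, a rolling-baseline operational definition of fatigue, and
a cross-validated comparison of fused multi-sensor prediction models
against single-indicator baselines. This vignette explains the models, the
synthetic cohort that stands in for non-shareable athlete data, the
numerical choices, and what the package's tests do and do not establish.

## Load indicators

**TRIMP.** Banister's heart-rate-weighted impulse
$\mathrm{TRIMP} = T \cdot \mathrm{HRr} \cdot a\,e^{b\,\mathrm{HRr}}$, where
$T$ is session duration (min) and
$\mathrm{HRr} = (HR_{mean}-HR_{rest})/(HR_{max}-HR_{rest})$ is the
fractional heart-rate reserve. The weighting constants default to the
male-form values $a = 0.64$, $b = 1.92$; the method's name alone does not
pin the constants, so they are explicit arguments. TRIMP is zero at zero
duration or resting heart rate and strictly increasing in both arguments —
properties the tests assert directly.

**sRPE.** The Borg CR-10 session rating times duration in minutes.
TRIMP and sRPE are both homogeneous of degree 1 in duration.

**Player Load.** The accumulated instantaneous rate of change of tri-axial
acceleration, $\sum_t \sqrt{\Delta a_x^2+\Delta a_y^2+\Delta a_z^2}/100$.
It is invariant to constant offsets (gravity, mounting) and additive over
concatenated traces up to the junction step. The package includes a toy
100 Hz trace generator purely to exercise this formula; raw accelerometry
is otherwise out of scope.

**EWMA ACWR.** Acute and chronic exponentially weighted moving averages of
the daily load with spans of 7 and 28 days, $\lambda = 2/(N+1)$, both
initialised at the first day's load, combined as the *uncoupled* ratio
acute/chronic. Initialising at the first observation (rather than zero)
avoids a start-up transient in which the ratio is undefined or explosive;
the all-zero history is mapped to ACWR = 1 by convention, which is the
fixed point under constant load. The daily load stream feeding ACWR,
monotony and strain defaults to summed daily sRPE and can be switched to
TRIMP in the configuration — the choice of stream is genuinely open in the
field, and both code paths are tested.

**Monotony and strain.** Weekly monotony is mean/SD of the seven daily
loads (sample SD, $n-1$); strain is weekly total × monotony. A week of
identical loads has zero SD; monotony and strain are then *flagged
undefined* (`NA`) rather than capped, because a capped value would silently
dominate any downstream average. In the athlete-day table these
"weekly" aggregates are computed over the trailing seven days ending the
*previous* day, so that every model feature is available on waking, before
that day's training (no look-ahead).

**Rolling baselines.** Individual baselines are means over the strictly
prior `window` days (default 7), emitted only when at least `min_obs = 3`
values contribute. Using strictly prior days keeps the current morning's
value out of its own baseline.

## The fatigue label

Four criteria are evaluated per athlete-day against individual baselines:

1. CMJ height drop **> 10%** versus the rolling mean of up to 4 prior
   weekly tests. CMJ is measured weekly but the criterion is daily, so the
   test-day evaluation is carried forward up to 6 days (until the next
   test); before the second test the criterion is not evaluable.
2. Morning LnRMSSD drop **> 0.5** (log scale, as conventionally reported)
   versus the individual 7-day rolling average.
3. Wellness total **< 15** of 25 (five 1–5 items: fatigue, sleep quality,
   soreness, stress, mood).
4. Maximum session RPE **≥ 8** on two *consecutive calendar days with
   sessions*; a rest day breaks the run.

A day is `fatigued` when at least two evaluable criteria are met,
`non_fatigued` otherwise, and `unlabelable` when fewer than two criteria
could be evaluated (such days are excluded from modelling rather than
imputed to non-fatigued — imputing them would bias prevalence downward and
teach the models that missingness means health). The thresholds are sharp
exactly as written: wellness 15 and a CMJ drop of exactly 10% do *not*
meet their criteria, RPE of exactly 8 does. Boundary behaviour,
monotonicity (meeting an extra criterion can never remove a fatigue
label), and purity (labels independent of row order) are property-tested.

## The synthetic cohort generator

The generator is a first-class, tested module, not a fixture. It emulates
a 48-athlete squad (3 GK / 15 DF / 18 MF / 12 FW) over a 12-week calendar
(progressive weeks 1–4, maintenance 5–10, taper 11–12; Monday recovery +
test day, Sunday rest, 24 matches on Saturdays and Wednesdays), with
training attendance ~95% per athlete.

**Latent state.** Each athlete carries a first-order fitness–fatigue
impulse response $F_t = F_{t-1}e^{-1/\tau} + \kappa L_t/100$ with
$\tau = 5$ d, $\kappa = 0.8$, driven by daily TRIMP. The latent state is
simulator plumbing that gives markers and labels a coherent joint
structure; nothing like it is estimated from data.

**Sessions.** Session channels (distances, counts, Player Load, HR
fraction, RPE, duration) are drawn from a Gaussian copula with
type-specific marginals (training vs match means/SDs of a published
collegiate cohort) truncated at physiological bounds, with multiplicative
position factors normalised to the squad mix so cohort-level marginals are
preserved (midfielders cover most distance, forwards lead high-speed and
sprint running, defenders lead decelerations). The copula's target matrix
is repaired to the nearest positive-definite correlation matrix by
eigenvalue clipping. Its entries were calibrated *once*, against the
observed session-level correlations of the generated tables (which pool
training and match sessions and include TRIMP computed downstream), to the
published heat-map structure — e.g. Player Load–TRIMP r ≈ 0.8,
total distance–Player Load ≈ 0.9, mean HR–TRIMP ≈ 0.9 — and then frozen.
Because observed TRIMP is a convex function of duration and HR fraction,
within-type copula entries differ from the pooled correlations they induce;
calibration was done on the induced values.

One deliberate inconsistency with the published descriptives: the printed
TRIMP means (186 training / 312 match) are not jointly attainable with the
printed heart rates (142/161 bpm against rest 58, max 196) under Banister
male constants at realistic session durations. The generator matches
heart-rate, duration and sRPE marginals and lets computed TRIMP fall where
the formula puts it (≈ 125 / 195 AU). Correlation targets are scale-free
and unaffected.

**Mornings.** LnRMSSD falls with the latent state
(β = 0.18 per unit), with the previous day's TRIMP (0.31 per 100 AU,
the acute autonomic response), and with a day-level recovery shock;
resting HR rises with fatigue; the five wellness items decline
analogously and are rounded and clamped to 1–5. The recovery structure is
a mixture: a latent "poor recovery day" indicator (logit-linear in fatigue
and previous-day load) shifts *both* the HRV and wellness channels, but
each channel realises its own shock magnitude. This is the key design
choice for construct validity of the model comparison: the shared
indicator creates the criterion co-occurrence needed for a realistic
~15% fatigue prevalence concentrated on days 1–2 after matches, while the
independent magnitudes prevent the wellness score from revealing the HRV
criterion — with a single shared shock, a wellness-only model matches the
fused model and the study's central contrast (fusion beats single
indicators) disappears from its own testbed.

In the cohort loop the marker couplings are applied as deviations from the
schedule's long-run latent level (≈ 5.4 units) and mean daily load
(≈ 124 AU), so marginal means stay at their configured values; the
exported single-record functions default these references to zero, which
gives the plain textbook forms (e.g. `cmj = baseline·(1 − 0.02·F)`).

**Weekly tests.** CMJ height declines 2% per latent unit plus noise;
the 10 m sprint time lengthens correspondingly; peak power scales with
jump height.

**Missingness.** Completely at random, per cell, at 5.4% per table by
default (matching a ~94.6% collection completeness). MCAR is an explicit
simplification — the mechanism of real monitoring missingness
(compliance, match travel) is not characterised here. Because realized
per-variable rates straddle the 5% tier boundary, both the mean-imputation
and the multiple-imputation QC paths are exercised by default.

**What passing tests do not show.** The generator reproduces marginals,
pairwise correlations, prevalence and post-match excess — not real
physiology: there are no injuries, no illness, no academic-stress
seasonality, no sensor drift, no non-random compliance, and the
fatigue label is generated by the same family of mechanisms the criteria
measure. Model AUCs on synthetic data are therefore upper bounds of a
deliberately self-consistent world; only *relative* statements (fusion vs
single indicators, subject-held-out vs pooled folds, feature ranking) are
meaningful, and those are what the tests assert.

## Quality control and assembly

Outliers are flagged beyond 3 SD of the mean, per athlete where at least
20 observations exist for the variable and cohort-wide otherwise (whether
the published rule was per-athlete is unstated; the hybrid avoids flagging
an athlete's normal range as outlying relative to the cohort). Flagged
cells become missing. Variables with < 5% missing are mean-imputed within
athlete; 5–20% go through chained stochastic-regression imputation with
m = 5 completed draws averaged into the modelling table (full Rubin
pooling is out of scope — the table feeds machine-learning models, not
variance estimates); athletes above 20% missing are dropped and reported.
The z-score standardisation is deliberately *not* applied globally:
parameters are fitted inside each cross-validation training fold and
applied to its test fold, trading faithfulness to the published global
z-scoring for an honest evaluation. A pure-noise leakage canary (AUC must
stay ≤ 0.55) guards this in the test suite.

## Model comparison harness

Four model kinds with fixed published hyperparameters: stratified-random
dummy (scored like any model; expected AUC 0.5), ridge logistic regression
(glmnet, `lambda = 1/n`, the unit-inverse-regularisation convention),
random forest (ranger, 500 trees, √p candidate features), gradient
boosting (xgboost, η = 0.1, depth 6, 100 rounds, subsample 0.8). Schemes:
stratified 10-fold (class-balanced, deterministic given seed) and
leave-one-subject-out, where each athlete's entire data are held out once
— the conservative estimate of generalisation to new individuals. Folds
whose training data are single-class are skipped with a warning.

AUC is the tie-corrected rank statistic (equal to brute-force pairwise
comparison, asserted to 1e-12 in tests). The AUC 95% CI is the normal
approximation over folds, mean ± 1.96·SD/√k — the CI method is a
reporting convention, not an inference claim. Class metrics use a 0.5
threshold; the Youden-optimal operating point (max sens + spec − 1, ties
broken toward higher specificity) is reported separately from the ROC.
No class-imbalance resampling is applied.

Attributions come from the full-data boosting fit: gain importances
normalised to percentages and exact path-dependent TreeSHAP contributions
on the margin scale. Local accuracy (contributions + base = margin) is
asserted per instance at 1e-6 *relative to the margin magnitude*, the
attainable precision given single-precision leaf weights.

## Numerical choices and degenerate inputs

- EWMA initialised at the first observation; all-zero load history gives
  ACWR = 1; oracle equivalence to the unrolled closed form at 1e-12.
- Zero-SD weeks: monotony/strain `NA` (flagged, never capped).
- Zone boundaries at 50/60/70/80/90% of HRmax; minutes below 50% are
  unzoned; zoned + unzoned always equals the series length.
- Constant columns: no outlier flags, z-scoring errors loudly, correlation
  cells become `NA` sentinels.
- Negative heart-rate recovery is returned as-is with a warning flag.
- Shapiro–Wilk gates (α = 0.05, subsampled at n > 5000) choose Pearson vs
  Spearman and pooled t vs Mann–Whitney; the pooled-variance t is the
  default reading of "independent samples t-test", with Welch by flag.
- Truncated-normal draws use the inverse-CDF form so vectorised generation
  consumes a fixed number of uniforms and stays bit-reproducible.

## Problem sizes

The shipped defaults are the study conditions: 48 athletes × 84 days
(4,032 person-days, ~2,800 athlete-sessions). The test suite runs the full
default cohort for calibration checks (5 seeds) and the directional model
comparison (10 seeds, including leave-one-subject-out), and smaller
engineered fixtures for exact-value oracles; the complete suite and the
acceptance script each finish in a few minutes on one CPU.

## Known limitations

- The calendar is deterministic (fixed match weekdays); match congestion
  varies only through the configured match count.
- One published inconsistency is left unresolved by design: the reported
  total of 536 training sessions and the reported 11.2 sessions per
  athlete-week cannot both hold for 48 athletes over 12 weeks; both
  scheduling knobs are exposed in the configuration.
- The dummy classifier's published metric row (accuracy 0.848 with
  sensitivity 0.152 and specificity 1.000) matches no single standard
  dummy strategy; the harness reports true stratified-dummy metrics and
  treats only its chance-level AUC as reproducible.
- Printed between-group effect sizes in the source material do not all
  follow from the printed means and SDs under the standard pooled-SD
  formula; `compare_groups()` always computes Cohen's d from data.
- Biochemical markers (salivary cortisol/testosterone) are excluded; they
  are optional in the operational definition and unused by the rule.
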