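---
title: "Methods: plantar-pressure gait features and functional-test prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plantar-pressure gait features and functional-test prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Knee-osteoarthritis patients show characteristic gait changes — reduced heel
loading, unstable and asymmetric stepping — and their functional status is
conventionally scored with supervised performance tests: the 40-m fast-paced
walk test (40mFPWT) and the timed up-and-go test (TUGT), both measured as a
completion time in seconds. `plantargait` implements a pipeline that predicts
those two times from pressure-sensing insoles: 8 sensors per foot sampled at
20 Hz, forefoot (sensors 1–4), midfoot (5–6) and heel (7–8) regions. The
pipeline segments gait cycles from the total vertical ground reaction force
(VGRF), extracts a 380-gait-feature + 4-physical-characteristic database,
reduces it by a stepwise selection cascade, and trains individual, stacked
and averaged ensemble regressors.

Because no patient recordings are distributed, every stage is validated
against a synthetic gait generator with known ground truth. This vignette
documents the models, the tunable parameters, and the design decisions taken
where the underlying methodology left choices open.

## Synthetic gait generator

Walking VGRF under one foot is bimodal in stance: a first peak from heel
loading, a mid-stance valley, a second peak from push-off, and no load in
swing. The generator builds each cycle's total-VGRF curve from piecewise
cubic Hermite segments with zero slope at the landmark knots
(heel strike 0, peak 1, valley, peak 2, stance end 0). Each segment is a
monotone smoothstep, so the sampled curve attains the planted amplitudes
exactly at the knots and is exactly zero through swing — important because
tests plant amplitudes and assert their recovery to machine precision.
An earlier draft used `stats::splinefun(method = "monoH.FC")`, but R's
Fritsch–Carlson slopes are not forced to zero at direction-change knots and
the interpolant overshoots planted peaks by a few percent; the zero-slope
Hermite form removes that artifact.

Defaults (per cycle, fractions of body weight, %BW): cycle duration
T = 1.1 s, stance fraction 0.62, peaks 1.15 and 1.10 %BW at 17% and 47% of
the cycle, valley 0.75 %BW — typical adult walking values. The total is
distributed across regions by a time-varying activation profile
(heel `(1−v)²`, midfoot `2v(1−v)`, forefoot `v²` over stance progress `v`,
weighted by region shares and renormalized per sample), so the regional
series sum to the total identically. Within regions, fixed per-sensor
shares split the load.

Variability and asymmetry:

* `cycle_jitter_sd` — fractional SD of per-cycle duration and amplitude
  jitter; both feet share the same draws, so with zero asymmetry the right
  channel matrix is exactly the left one shifted by the programmed
  half-cycle phase offset.
* `asym_amp`, `asym_time` — right-foot amplitude and stance-duration
  scaling, producing nonzero symmetry-index features.
* The right foot is offset by half a cycle; with stance fraction > 0.5 this
  creates genuine double-support intervals.

### Cohort and label model

`cohort_spec()` fixes the study conditions: 92 participants; age
62.95 (SD 8.4) years truncated to [45, 85], height 158.08 (SD 7.85) cm,
weight 61.33 (SD 10.47) kg (an elderly, predominantly female
knee-osteoarthritis cohort), per-participant cycle duration
1.1 (SD 0.08) s, stance fraction 0.62 (SD 0.02), half-normal amplitude
asymmetry (SD 0.04) and uniform cycle jitter SD in [0.01, 0.05].

Labels are linear in gait parameters and physical covariates with Gaussian
noise — the simplest structure that supports recovery experiments:

* 40mFPWT: `−25 + 8·T + 10·stance + 20·asym + 0.6·age + ε`, ε ~ N(0, 1.5²)
* TUGT: `−10.5 + 3·T + 4·stance + 10·asym + 0.25·age + ε`, ε ~ N(0, 0.8²)

Coefficients were chosen once so the simulated label distributions match the
reported cohort scales (≈28.6 (SD 6.2) s and ≈11.4 (SD 3.0) s) with age as
the dominant predictor — consistent with age emerging as the most relevant
feature in the clinical analysis. The generator returns which gait
parameters carry signal (`signal_params`), so selection and full-pipeline
recovery can be tested against ground truth.

What the generator does *not* emulate: sensor noise and drift, turning
strides in a corridor walk, disease-grade-specific waveform shapes, and
nonlinear parameter–outcome relationships. Passing tests therefore
demonstrate correctness of the computational pipeline and its ability to
recover planted linear signal, not clinical validity on real patients.

## Segmentation

Heel strikes are sustained upward crossings of a detection threshold on the
total VGRF — 5% of the recording's maximum by default, with a two-sample
hysteresis so single-sample noise spikes cannot trigger a strike at 20 Hz.
Toe-off is the first subsequent sample back below the threshold; the cycle
ends at the next heel strike (half-open span, 1-based sample indices — the
R convention). Within stance, the two largest local maxima in temporal
order are the VGRF peaks (plateau/tie broken to the earliest sample) and
the minimum between them the valley. Stances with fewer than two local
maxima are excluded with a warning rather than fabricating a valley, since
the feature definitions presume the bimodal pattern. The trailing
incomplete cycle is discarded.

The analysis window excludes the first 2 starting steps per foot and keeps
the next 50 cycles, pairing each left cycle with the first right cycle whose
heel strike falls inside it (or whose stance overlaps it); recordings
therefore need at least 52 complete cycles per foot.

## Feature database

Per cycle and foot, 54 features in five families (names carry `L_`/`R_`
prefixes):

* **PPP** (15): per-sensor maxima, summed-regional maxima (the regional
  series is summed before taking the maximum), the two total-VGRF peak
  amplitudes, and the lateral/medial peak ratios 4/2 (forefoot) and 8/7
  (heel). Zero-denominator ratios are flagged missing.
* **PG** (25): max/min discrete derivative per sensor and per regional
  series (%BW/s); loading rate (heel strike → peak 1 of the total curve);
  off-loading rate (peak 2 → toe-off, stored signed, hence negative);
  valley gradient sum Σ|ΔP/Δt| between the peaks.
* **Temporal** (5): stance/swing ratio, cycle time, stance fraction, and
  the two peak-time fractions.
* **PTI** (2): trapezoidal pressure–time integrals, heel strike → peak 1
  and over stance (%BW·s).
* **COP** (7): per-sample pressure-weighted mean of the normalized sensor
  coordinates over above-threshold stance samples; mean/SD of both
  coordinates, trajectory length, and mean/SD of the resultant distances
  measured from the stance-mean COP point (the fall-risk-literature
  convention for MRD/SRD).

Two bipedal temporal features (single- and double-limb support time) use
both feet's threshold crossings over the left-anchored cycle span. The 110
per-cycle values are averaged over the 50 cycles; the 108 single-foot
features additionally get sample SDs (n−1; the population/sample choice is
not prescribed anywhere, sample SD is this package's convention) with the
`_STD` suffix. From the cycle means:

* **Symmetry index** (54): the Robinson form
  `SI = |L − R| / (0.5 (L + R)) × 100`. Any reasonable variant preserves
  the properties relied on downstream (SI = 0 at symmetry, symmetry in
  arguments, monotone growth with discrepancy).
* **Weak foot** (108): the foot with larger cycle-averaged
  anterior-posterior COP variability (`ycop_std`) is labelled weak — ties
  resolve to the left foot — and its 54 means and 54 SDs are copied with
  the `W_` prefix.

With age, height, weight and BMI this gives the canonical 384-column
participant vector; `assemble_features()` fails loudly on any inventory
mismatch. Missing per-cycle values are excluded from means/SDs; any
participant-level missing value is mean-imputed with training-split
statistics before modelling.

## Selection cascade

All statistics are computed on the training split of a 67/33 holdout
(92 → 61/31; the test count is `ceiling(0.33·n)`, matching the reported
31-case test set). Stages:

1. **Spearman filter**: keep features with |ρ| ≥ 0.2 against the task
   label (ties at the threshold retained; constant features dropped).
2. **mRMR**, MID variant for a continuous target: relevance = |Pearson r|
   with the label, redundancy = mean |Pearson r| with already-selected
   features, greedy score = relevance − redundancy. Capped at the training
   sample count. With redundancy weight 0 it reduces to top-k relevance,
   which the tests assert.
3. **Floating wrapper** (SFFS/SBFS): conditional add/remove steps scored
   by mean 5-fold CV MAE of a seeded random forest (MAE is the primary of
   the three reported metrics; the wrapper metric is not prescribed).
   The best subset over all visited sizes is returned, and the cascade
   guarantees final ⊆ mRMR ⊆ Spearman.

A PCA benchmark (components by a 95% explained-variance threshold by
default, features z-scored with training-fold statistics) provides the
comparison baseline; on sparse planted signal the cascade's CV error is
expected to undercut it, which the acceptance suite checks directionally.

## Models and ensembles

Six individual regressors: linear regression, RBF-kernel SVM, random
forest, AdaBoost.R2 (the classic boosting-for-regression algorithm,
implemented over `rpart` trees with weighted-median prediction), a
depth-wise gradient-boosted tree model (`xgb`), and a
leaf-wise histogram-binned gradient booster (`lgb`, realized through
xgboost's `grow_policy = "lossguide"`/`tree_method = "hist"`
configuration — the LightGBM-style growth strategy). Hyperparameters are
tuned by seeded random search (default budget 8–10 draws) over documented
spaces, scored by 5-fold CV MAE on shared unstratified shuffled folds;
reported metrics are fold-averaged MAE/MAPE/RMSE of the winning
configuration.

The **baseline** predicts the training-label mean; the **relative index**
of a model is `RI = Σ_m (baseline_m − model_m) / baseline_m` over the three
metrics, so the baseline scores 0 and a model that halves every metric
scores 1.5.

The **stacked model** uses the four tree members at the first level.
Within each outer training split, inner 5-fold out-of-fold member
predictions form the n×4 second-level design matrix; the second level is
linear or an RBF SVM; outer validation folds — never seen by any member —
score the stack. The out-of-fold construction is what the leakage tests
verify: perturbing held-out rows changes nothing.

**SAE** averages the four tree members equally; **WAE** weights them by
their RI proportions computed from training CV. Members with nonpositive
RI are excluded from WAE (a proportional weight is undefined for them)
rather than given negative weight; if no member has positive RI the WAE is
not constructed. With equal member RIs, WAE and SAE coincide exactly.

## Numerical choices and test problem sizes

* Sampling is fixed at 20 Hz (Δt = 0.05 s) throughout.
* Detection threshold 5% of maximum total VGRF with 2-sample hysteresis.
* Peak ties break to the earliest sample; weak-foot ties to the left foot.
* Every stochastic stage takes an explicit seed; cohort generation, fold
  assignment, hyperparameter search and tree fits are reproducible to the
  byte, and package functions restore the caller's RNG state.
* The test suite exercises recovery at the scales a desk validation
  supports: planted-signal cohorts of n = 100 with 20 replicate seeds for
  the selection-cascade and full-pipeline experiments, 200 replicates for
  the Spearman retention rate, and 100 random cycles for the brute-force
  oracle comparisons. The analysis scripts run the full 92-participant
  roster with mRMR capped at 30 features and wrapper subsets up to 15.

## Limitations

* The synthetic waveform family is smooth and noise-free; segmentation
  robustness to hardware noise is covered only via the hysteresis design,
  not empirically.
* Label–parameter coupling is linear; the ensembles' advantage over linear
  models on real, nonlinear gait–function relationships cannot be
  demonstrated on this generator (and indeed linear models are competitive
  on the synthetic cohort).
* Published per-cohort error magnitudes depend on the undeposited patient
  data; only the relative-index arithmetic, inventory counts and split
  arithmetic are reproduced exactly.
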