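---
title: "Predicting CKD progression from longitudinal EHR time series"
author: "ckdprog"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting CKD progression from longitudinal EHR time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Chronic kidney disease (CKD) is staged by the estimated glomerular
filtration rate (eGFR, mL/min/1.73m²): stage II is 60–89, stage III is
30–59 (IIIa 45–59, IIIb 30–44), and stages IV/V are 29 and below. Most
early-stage patients never progress; a minority decline rapidly into the
late stages, where morbidity, mortality and treatment costs rise sharply.
`ckdprog` implements a complete pipeline for predicting whether a patient
currently in stages II/III will progress to a *stable* stage IV/V state
within a chosen horizon, using nothing but routinely collected,
irregularly timed EHR observations.

The pipeline has five stages — stable-period detection and case/control
assignment, time-series assembly, case-control matching, model fitting
(an LSTM recurrent network plus four standard baselines), and a repeated
cross-validation harness — plus a sequential forward variable-selection
procedure and a synthetic EHR generator that makes every stage testable
without access to protected health data.

## Cohort definitions

A **stable period** in an eGFR band is a span of at least 90 days in
which *every* reading lies inside the band, anchored by two in-band
readings at least 90 days apart. `find_stable_episodes()` implements
this as maximal in-band runs whose time span reaches 90 days; this is
provably equivalent to the anchor-pair definition (the test suite checks
exact agreement with a brute-force oracle that enumerates all reading
pairs), and all band bounds are inclusive.

Study entry requires at least one stable stage II/III period (eGFR in
[30, 89]) and at least four eGFR readings. An eligible patient is a
**case** if a stable stage IV/V period (eGFR ≤ 29) exists and neither of
the first two readings falls inside one; the **transition point**
`T_tra` is the time of the first reading of the earliest such period.
Eligible patients with no stable stage IV/V period are **controls**.
Exclusions carry a reason code (`too_few_egfr`,
`no_stable_early_period`, `first_readings_in_late_period`).

Whether the entry criterion should additionally require the stable
II/III period to *precede* all late-stage data is not decidable from the
definitions alone; we require only its existence, and the
first-two-readings rule already excludes patients whose record starts in
the late stage.

## Time-series assembly

Observations are binned onto half-open weekly intervals
`[k·t_w, (k+1)·t_w)` anchored at `t = 0` (each patient's record start;
the generator emits the first visit at `t = 0`). Interval `n` is stamped
with its midpoint `T_n = (n − 0.5)·t_w`, which is also appended to the
feature vector as the *time feature*. Within an interval, laboratory and
vital values are arithmetic-averaged, health-behavior codes take the
latest reading, and demographics are constant columns. Empty intervals
between observed ones are kept as grid rows (missing, later imputed)
so the time step stays uniform.

For a case, every time point at or past `T_tra − t_gap` is discarded:
the gap period (`t_gap`, default 7 days) prevents the label from leaking
through measurements that themselves establish the transition. A case is
valid only if at least `min_case_len = 5` points remain and the
transition falls inside the prediction window measured from the last
used point: `t_gap ≤ T_tra − T_last ≤ t_pre`. For a control, the final
`t_pre` days of feature vectors are removed, so the retained prefix is
known progression-free for at least the prediction horizon. Sequences
are then truncated to the latest `max_len = 100` points, which produces
the characteristic atom at length 100 in the case-length distribution.
Valid cases are labeled 1, retained controls 0.

The **stage-IIIb exclusion** variant emulates the harder task of
predicting from stages II/IIIa only: each patient's observation stream is
truncated at the first eGFR reading ≤ 44 before assembly. Case status
and `T_tra` are still determined from the full series — only window
validity is re-evaluated on the truncated stream. The alternative
reading (drop only the IIIb-period rows but keep later history) would
feed the models post-IIIb information and cannot reproduce the sharp
loss of valid patients this variant is known for, which is why
truncation was chosen.

**Imputation** is a training-fold operation: last-observation-carried-
forward, then next-observation-carried-backward, then the
training-population median — chosen for auditability (the pre-imputation
mask is preserved on every series). Continuous features are z-scored
with training-fold mean/sd before modeling; statistics never flow from
validation or test patients.

## Matching

Each valid case is matched with up to four controls that agree exactly
on race, sex and sequence length and fall within ±5 years of age, ranked
by age gap (ties broken by patient id), greedily in a seeded random case
order and without replacement. Age is taken at the last used time point
(`age_at_start + T_last / 365.25`). Cases that attract no controls are
retained with a diagnostic flag — dropping them would bias the dataset
toward strata rich in controls. Greedy matching attains the optimal
total match count whenever stratum capacities are the binding
constraint, which the tests verify against a closed-form capacity
oracle; pathological age configurations where a globally optimal
bipartite assignment beats greedy are possible in principle but are not
a concern at the cohort sizes used here.

## Models

All five models expose one contract: a risk score in [0, 1], higher
meaning higher predicted progression risk, deterministic under a fixed
seed.

**LSTM.** A single LSTM layer reads the padded, masked sequence of
feature vectors; its final state feeds a stack of ReLU dense layers with
dropout and a 2-node softmax. Training minimizes weighted cross-entropy —
control weight 1, case weight equal to the control/case count ratio of
the training fold — with Adam (learning rate 1e-3, batch 64), both
fixed for reproducibility. The dropout rate is the only tuned
hyper-parameter: each rate on the grid {0, 0.1, 0.2, 0.3, 0.4, 0.5, 0.7}
is trained with early stopping on validation loss (the monitored
quantity; patience-limited) and the rate with the lowest validation loss
wins. Sequences are pre-padded (right-aligned) to `max_len` with an
explicit mask, so the recurrent state is frozen during padding steps.
The implementation (forward pass, backpropagation through time, Adam) is
in C++ via RcppArmadillo, with all randomness drawn from R's RNG so
`set.seed()` reproduces training exactly. Restricting the grid to {0}
with unlimited patience reduces the procedure to plain weighted
cross-entropy training (an ablation hook used in tests). The
all-variables variant defaults to 64 units and dense sizes 64-32-16; the
essential-variables variant to 32 units and one dense layer of 16 — only
the architectural shape (one LSTM layer, then dense layers, fewer and
smaller for the reduced input) is fixed; all sizes are configurable.

**Cox models.** The static Cox proportional hazards baseline uses each
patient's covariates at the first time point; cases contribute the event
at `T_tra − T_1`, controls are censored at `T_last + t_pre − T_1` — the
end of the span they are known progression-free, the natural censoring
time for this design. The dynamic Cox model organizes each patient as
counting-process rows, one per grid interval (the final row extended to
the event/censoring time), with demographics time-independent and
clinical variables time-dependent. Both are fitted with
`survival::coxph` on the merged training + validation folds (no
hyper-parameters to tune). Risk is `1 − S(horizon)` via the Breslow
baseline hazard; the dynamic model evaluates it at the last observed
covariate vector (a prediction-time convention, since a full
time-forward integration of future covariate paths is not identified).
The grid-time feature is excluded from Cox covariates — it is the time
axis itself (and is constant at `T_1` in the static design anyway);
constant columns are dropped with a message. If the chosen horizon
precedes the first training event, the cumulative baseline hazard there
is zero and every predicted risk would degenerate to exactly 0; the
implementation then falls back to the earliest positive baseline hazard
(with a message), which keeps the scores monotone in the linear
predictor.

**Snapshot baselines.** Random forest and gradient-boosted trees
(xgboost) are trained on each patient's latest feature vector including
the time feature. The random forest merges training and validation
folds; the boosted model uses the validation fold to early-stop its
boosting rounds.

## Evaluation

`run_trials()` repeats a stratified ten-fold partition: eight folds
train, one validates, one tests, with one random role assignment per
trial (rotating the test fold through all ten positions is a
straightforward extension, but a single assignment keeps many trials
tractable and each trial independent). Folds are stratified by label
and, by default, keep each matched case-control set inside a single fold
so near-twin controls of a test case never appear in its training data.
Metrics are AUROC (midrank/Mann-Whitney), AUPRC (step-wise average
precision over distinct thresholds), and MCC at a 0.5 cutoff (defined as
0 on degenerate tables); race-stratified AUROC is computed per test fold
with single-class strata skipped and counted. The full analysis design
uses 100 trials; the bundled experiments use 5 (and 10 for selection) so
the whole suite runs on one CPU in minutes — the means are the same
estimand, with wider Monte-Carlo error.

## Variable selection

`forward_select()` starts from the time feature (always included) and
adds one variable per step. Within each trial, every remaining candidate
is tried and the one maximizing test-fold AUROC is chosen — trials may
disagree, and the per-step selection frequencies quantify exactly that.
The per-step AUROC distribution is compared against the all-variables
model on the same partitions by a two-sided paired t-test (identical
vectors return p = 1 with a degenerate-variance flag), adjusted across
steps by Benjamini–Hochberg. With every variable selected, the final
step spans the same feature set as the all-variables reference; their
AUROCs then agree in expectation, though not to the digit, because the
two fits consume different random-number streams.

## The synthetic generator

The generator emulates the statistical structure the analysis assumes,
not any real cohort:

* **Visit process:** inter-visit gaps are 1 day + Gamma(shape 2) with a
  mean of 30 days — irregular, strictly positive, clinic-like.
* **Trajectories:** latent eGFR is linear in time with Gaussian
  measurement noise (sd 3), truncated below at 5. Progressors (fraction
  0.15) draw slopes from N(−12, 4²) mL/min/1.73m²/yr (floored at −2);
  non-progressors from N(−1, 1.5²), floored so the expected trajectory
  stays ≥ 35 — without that floor, measurement noise around a
  borderline trajectory can fabricate stable stage IV/V periods in
  patients meant to be controls. A progressor's record ends 270–450 days
  after its expected eGFR-29 crossing: long enough to establish the
  stable late period, short enough to stay clear of the floor (which
  would otherwise flatten recovered slopes).
* **Entry conditioning:** the first eGFR reading is resampled into
  [30, 89] — patients enter an early-stage cohort when they are
  *observed* in stages II/III, so conditioning the entry measurement is
  the realistic choice and makes the baseline range [45, 80] safe under
  noise.
* **Covariates:** serum creatinine is inversely monotone in latent eGFR
  (≈ 75/eGFR plus noise); hemoglobin, bicarbonate and phosphorus couple
  to eGFR the way anemia, acidosis and hyperphosphatemia accompany
  declining kidney function; blood pressures, BMI, albumin and uric acid
  are stationary patient-level signals; behaviors (smoking, alcohol,
  drug use) are 2-state Markov chains with stay probability 0.95.
  Setting `correlated_covariates = FALSE` severs every eGFR coupling,
  confining the predictive signal to eGFR alone — the configuration
  under which forward selection is expected to recover eGFR first.
* **Missingness:** each non-demographic observation is dropped
  independently with probability 0.2 (MCAR); the entry eGFR is always
  kept. Informative missingness is out of scope.
* **Follow-up:** uniform between 1.5 and 5 years. Ages are N(62, 12²)
  clipped to [25, 90]; the race mix (55% African American, 30% white,
  15% others) mirrors an urban medical-center population enriched for
  minority patients.

What passing tests on this generator do *not* show: real EHRs have
informative visit timing and missingness, non-linear and change-point
trajectories, coding artifacts, and label noise in eGFR itself. The
generator validates the *pipeline logic and the relative behavior of the
models*, not clinical performance; absolute synthetic AUROCs are
optimistic because a linear latent trajectory is close to the best case
for every model considered.

## Problem sizes and defaults used in the bundled experiments

The packaged experiments (test suite and `scripts/acceptance.R`) use a
2,000-patient cohort, eGFR-only features, 5 cross-validation trials with
the essential-variant LSTM (32 units, one dense layer of 16, dropout
grid {0, 0.3}, ≤ 30 epochs, patience 5), and a 600-patient
uncorrelated-covariate cohort with 10 trials for the selection
experiment. These sizes make every experiment reproducible on a single
CPU while leaving the estimands unchanged; the full dropout grid and
100-trial design remain the defaults of `lstm_config()` and the
documented analysis configuration for real data.

## Known limitations

* Greedy matching is order-dependent; the seed fixes the order, and an
  optimal-assignment matcher would differ only in adversarial pools.
* The dynamic Cox prediction uses last-known covariates; other
  conventions (landmarking, joint models) are out of scope.
* MCAR imputation and z-scoring are deliberately simple; model-based
  imputation would blur the audit trail the mask provides.
* The LSTM trainer is single-threaded; at the bundled problem sizes this
  is minutes of CPU, but the full 100-trial, 7-rate design on a large
  cohort is an overnight job.
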