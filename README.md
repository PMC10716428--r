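# ckdprog

Predicting chronic kidney disease (CKD) progression from stages II/III to
stages IV/V using longitudinal electronic health records (EHRs).

CKD is staged by the estimated glomerular filtration rate (eGFR,
mL/min/1.73m²): stage II 60–89, stage III 30–59, stages IV/V ≤ 29. Early
identification of the minority of early-stage patients who will decline
into the late stages drives referral, treatment-intensification and
monitoring decisions — but plain stage labels ignore the trajectory a
patient's repeated eGFR measurements trace out. `ckdprog` is aimed at
biostatisticians and clinical-informatics researchers who want a complete,
reproducible pipeline from raw long-format EHR observations to evaluated
risk models:

1. **Cohort construction** — a *stable period* in a stage band is a span of
   ≥ 90 days in which every eGFR reading stays in band (two anchor readings
   ≥ 90 days apart, nothing out-of-band between). Patients with a stable
   stage II/III period and ≥ 4 eGFR readings enter; a stable stage IV/V
   period makes a patient a case, with transition point `T_tra` at the
   period's first reading.
2. **Time-series assembly** — observations are binned onto weekly intervals
   (midpoint `T_n = (n − 0.5)·t_w` appended as a time feature; labs/vitals
   averaged, behaviors latest-in-interval). Cases keep only the history
   before `T_tra − t_gap` and must have the transition inside the prediction
   window: `t_gap ≤ T_tra − T_last ≤ t_pre`. Controls lose their final
   `t_pre` span. Sequences are truncated to the latest 100 points.
3. **Matching** — each case is matched with up to 4 controls agreeing
   exactly on race, sex and sequence length, nearest in age (±5 years),
   greedily without replacement.
4. **Models** — an LSTM sequence classifier (single LSTM layer → ReLU dense
   stack with dropout → 2-node softmax) trained with weighted cross-entropy

   &nbsp;&nbsp; *L* = −(1/Σwᵢ) Σᵢ wᵢ log p(yᵢ | xᵢ), wᵢ = 1 for controls,
   wᵢ = n₀/n₁ for cases,

   the dropout rate tuned on a validation fold over
   {0, 0.1, 0.2, 0.3, 0.4, 0.5, 0.7} with early stopping; plus four
   baselines behind the same scoring contract: static Cox proportional
   hazards (first-time-point covariates), dynamic Cox (counting-process
   rows, time-dependent covariates), random forest and gradient-boosted
   trees (latest feature vector).
5. **Evaluation** — repeated stratified 10-fold cross-validation
   (8 train / 1 validation / 1 test), AUROC, AUPRC, MCC at a 0.5 cutoff,
   race-stratified AUROC, and sequential forward variable selection with
   per-step selection frequencies and Benjamini–Hochberg-adjusted paired
   t-tests against the all-variables model.

Because real EHR cohorts of this kind are proprietary, the package includes
a synthetic longitudinal EHR generator (`generate_cohort()`) with latent
linear eGFR trajectories, a progressor subpopulation, correlated labs and
vitals, Markov-chain health behaviors, irregular visits and missingness —
every stage of the pipeline is exercised end-to-end on data you can
regenerate from a seed. The LSTM itself (masked forward pass,
backpropagation through time, Adam, dropout, early stopping) is implemented
in C++ via RcppArmadillo, with all randomness drawn from R's RNG so
`set.seed()` reproduces training exactly.

## Worked example

```r
library(ckdprog)

cohort <- generate_cohort(generator_config(n_patients = 500, seed = 1))
cohort
#> Synthetic CKD cohort: 500 patients, 219435 observations, 70 latent progressors

assignments <- build_cohort(cohort)
table(assignments$status)
#>    case control
#>      69     431

matched <- build_matched_dataset(cohort, spec = match_spec(seed = 1),
                                 variables = "egfr")   # eGFR-only features
matched
#> CKD modeling dataset: 221 patients ( 69 cases / 152 controls ), 2 feature columns

results <- run_trials(matched,
                      models = c("lstm", "random_forest", "cox_static"),
                      plan = cv_plan(n_trials = 3, seed = 2),
                      lstm_cfg = lstm_config("essential_variables",
                                             lstm_units = 32,
                                             dense_layer_sizes = 16L,
                                             dropout_grid = c(0, 0.3),
                                             max_epochs = 30, patience = 5))
summarize_trials(results)
#>           model auroc_mean auroc_sd auprc_mean auprc_sd mcc_mean   mcc_sd n_trials
#> 1    cox_static      0.892    0.102      0.818    0.212        0 0.00e+00        3
#> 2          lstm      1.000    0.000      1.000    0.000        1 1.92e-16        3
#> 3 random_forest      1.000    0.000      1.000    0.000        1 1.92e-16        3
```

Reading the output: 69 of the 500 synthetic patients develop a stable
stage IV/V period and survive the windowing rules; matching attaches 152
controls. On eGFR-only sequences the LSTM separates the held-out test folds
perfectly at this (easy, linear-trajectory) synthetic difficulty, while the
static Cox baseline — which sees only each patient's first feature vector —
trails with mean AUROC 0.892. The MCC of the Cox model is 0 because its
predicted 365-day risks stay below the 0.5 cutoff (a degenerate confusion
table scores 0), mirroring the characteristic weakness of absolute-risk
thresholding for rare outcomes. On larger cohorts (2,000 patients) the
full five-model comparison reproduces the expected ordering: LSTM above
random forest and gradient boosting, dynamic Cox above static Cox.

Forward variable selection on a cohort whose covariates are decoupled from
kidney function (`correlated_covariates = FALSE`) recovers eGFR as the
first-selected variable in 100% of trials:

```r
path <- forward_select(matched_all_variables,
                       cv_plan(n_trials = 10, seed = 11), max_steps = 1)
path$frequencies[[1]]
#> egfr
#>    1
```

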