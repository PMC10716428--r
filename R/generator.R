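#' Clinical variable catalog for the synthetic EHR generator
#'
#' Returns the catalog of longitudinal clinical variables emitted by
#' [generate_cohort()], one row per variable, tagged with its category
#' (`"lab"`, `"vital"`, `"behavior"`) and whether it belongs to the
#' *essential* variable set (demographics and vitals, the highest-frequency
#' labs, and the primary health-behavior indicators). Demographic variables
#' (sex, race) are static per patient and are carried in the cohort's static
#' table rather than in the long observation table.
#'
#' Behavior variables are 2-state integer codes: 0 = non-user / never,
#' 1 = current user.
#'
#' @return A data frame with columns `variable`, `category`, `essential`.
#' @export
default_variable_catalog <- function() {
  data.frame(
    variable = c("egfr", "creatinine", "hemoglobin", "bicarbonate",
                 "phosphorus", "albumin", "uric_acid",
                 "sbp", "dbp", "bmi",
                 "smoking_status", "alcohol_use", "drug_use"),
    category = c(rep("lab", 7), rep("vital", 3), rep("behavior", 3)),
    essential = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE,
                  TRUE, TRUE, TRUE,
                  TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic longitudinal EHR generator
#'
#' Defines the statistical structure of a synthetic CKD cohort: a
#' subpopulation of *progressors* whose latent eGFR trajectory declines into
#' the stage IV/V range (eGFR <= 29) during follow-up, and non-progressors
#' whose kidney function stays roughly stable. All patients start in CKD
#' stages II/III.
#'
#' Latent eGFR follows a patient-specific line
#' `baseline + slope * t / 365` with i.i.d. Gaussian measurement noise on
#' each reading, truncated below at 5 mL/min/1.73m^2. A progressor's
#' record ends 270-450 days after the expected eGFR-29 crossing of its
#' trajectory — long enough to establish a 90-day stable stage IV/V
#' period, short enough that the trajectory stays clear of the eGFR
#' floor; non-progressor slopes are floored so the expected trajectory
#' stays at or above eGFR 35 through follow-up.
#'
#' @param n_patients Number of patients.
#' @param progressor_fraction Probability a patient is a progressor.
#' @param baseline_egfr_range Range (min, max) of baseline eGFR in
#'   mL/min/1.73m^2; must lie within \[30, 89\] so all patients start in
#'   stages II/III.
#' @param slope_progressor Mean and sd (length-2 vector, mL/min/1.73m^2 per
#'   year) of the annual eGFR change for progressors; mean must be negative.
#' @param slope_nonprogressor Mean and sd of the annual eGFR change for
#'   non-progressors.
#' @param egfr_noise_sd Measurement noise sd on each eGFR reading.
#' @param visit_gap_mean_days Mean inter-visit interval in days; gaps are
#'   drawn as 1 day plus a Gamma(shape = 2) variate.
#' @param followup_days_range Range (min, max) of follow-up duration in
#'   days; the minimum must exceed 180 days so stable periods are
#'   constructible.
#' @param missingness_rate Probability each non-demographic observation is
#'   independently omitted (missing completely at random). The first eGFR
#'   reading is always kept (it is the study-entry observation).
#' @param variable_catalog Data frame as returned by
#'   [default_variable_catalog()].
#' @param correlated_covariates If `TRUE` (default) labs and vitals are
#'   coupled to the latent eGFR level (serum creatinine inversely monotone
#'   in eGFR; anemia, acidosis and hyperphosphatemia develop as eGFR
#'   falls). If `FALSE` every covariate other than eGFR is generated
#'   independently of kidney function, confining the predictive signal to
#'   eGFR alone.
#' @param seed Integer seed; identical config + seed reproduces the cohort
#'   exactly.
#' @return An object of class `ckd_generator_config`.
#' @export
generator_config <- function(n_patients = 2000,
                             progressor_fraction = 0.15,
                             baseline_egfr_range = c(45, 80),
                             slope_progressor = c(-12, 4),
                             slope_nonprogressor = c(-1, 1.5),
                             egfr_noise_sd = 3,
                             visit_gap_mean_days = 30,
                             followup_days_range = c(540, 1825),
                             missingness_rate = 0.2,
                             variable_catalog = default_variable_catalog(),
                             correlated_covariates = TRUE,
                             seed = 1L) {
  cfg <- list(
    n_patients = as.integer(n_patients),
    progressor_fraction = progressor_fraction,
    baseline_egfr_range = baseline_egfr_range,
    slope_progressor = slope_progressor,
    slope_nonprogressor = slope_nonprogressor,
    egfr_noise_sd = egfr_noise_sd,
    visit_gap_mean_days = visit_gap_mean_days,
    followup_days_range = followup_days_range,
    missingness_rate = missingness_rate,
    variable_catalog = variable_catalog,
    correlated_covariates = isTRUE(correlated_covariates),
    seed = as.integer(seed)
  )
  class(cfg) <- "ckd_generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  num <- unlist(cfg[c("progressor_fraction", "baseline_egfr_range",
                      "slope_progressor", "slope_nonprogressor",
                      "egfr_noise_sd", "visit_gap_mean_days",
                      "followup_days_range", "missingness_rate")])
  if (any(!is.finite(num)))
    stop("generator config contains non-finite values")
  if (cfg$n_patients < 0)
    stop("n_patients must be non-negative")
  if (cfg$n_patients == 0 && cfg$progressor_fraction > 0)
    stop("progressor_fraction > 0 requires n_patients > 0")
  if (cfg$progressor_fraction < 0 || cfg$progressor_fraction > 1)
    stop("progressor_fraction must be in [0, 1]")
  if (cfg$missingness_rate < 0 || cfg$missingness_rate > 1)
    stop("missingness_rate must be in [0, 1]")
  r <- cfg$baseline_egfr_range
  if (r[1] < 30 || r[2] > 89 || r[1] > r[2])
    stop("baseline_egfr_range must lie within [30, 89]")
  if (cfg$followup_days_range[1] <= 180)
    stop("followup minimum must exceed 180 days")
  if (cfg$slope_progressor[1] >= 0)
    stop("slope_progressor mean must be negative")
  if (cfg$visit_gap_mean_days <= 1)
    stop("visit_gap_mean_days must exceed 1 day")
  req <- c("variable", "category", "essential")
  if (!all(req %in% names(cfg$variable_catalog)))
    stop("variable_catalog must have columns variable, category, essential")
  invisible(cfg)
}

# Simulate a 2-state Markov chain of length n with stay probability p_stay.
markov_chain <- function(n, p_init, p_stay) {
  s <- integer(n)
  s[1] <- rbinom(1, 1, p_init)
  if (n > 1) {
    flips <- runif(n - 1) > p_stay
    for (k in 2:n) s[k] <- if (flips[k - 1]) 1L - s[k - 1] else s[k - 1]
  }
  s
}

#' Generate a synthetic longitudinal EHR cohort
#'
#' Simulates a CKD cohort per the supplied [generator_config()]: irregular
#' clinic visits (inter-visit gaps 1 day + Gamma with the configured mean),
#' a linear-with-noise latent eGFR trajectory per patient, correlated labs
#' and vitals, 2-state Markov-chain health behaviors, and per-observation
#' MCAR missingness. Time `t` is measured in days since each patient's
#' record start (first visit at `t = 0`).
#'
#' @param config A `ckd_generator_config`.
#' @return An object of class `ckd_cohort`: a list with
#'   \describe{
#'     \item{observations}{long-format data frame `(patient_id, variable,
#'       t, value)`, sorted by patient, variable, time}
#'     \item{static}{per-patient data frame `(patient_id, sex, race,
#'       age_at_start)`; `sex` is `"female"`/`"male"`, `race` one of
#'       `"African American"`, `"white"`, `"others"`}
#'     \item{ground_truth}{data frame `(patient_id, progressor)` — the
#'       generator's latent flag, never consumed by the pipeline}
#'     \item{config}{the generating configuration}
#'   }
#' @export
generate_cohort <- function(config) {
  validate_generator_config(config)
  set.seed(config$seed)
  n <- config$n_patients
  cat <- config$variable_catalog

  if (n == 0) {
    empty_obs <- data.frame(patient_id = character(), variable = character(),
                            t = numeric(), value = numeric(),
                            stringsAsFactors = FALSE)
    out <- list(observations = empty_obs,
                static = data.frame(patient_id = character(), sex = character(),
                                    race = character(), age_at_start = numeric(),
                                    stringsAsFactors = FALSE),
                ground_truth = data.frame(patient_id = character(),
                                          progressor = logical(),
                                          stringsAsFactors = FALSE),
                config = config)
    class(out) <- "ckd_cohort"
    return(out)
  }

  ids <- sprintf("P%05d", seq_len(n))
  progressor <- runif(n) < config$progressor_fraction
  sex <- ifelse(runif(n) < 0.5, "female", "male")
  race <- sample(c("African American", "white", "others"), n,
                 replace = TRUE, prob = c(0.55, 0.30, 0.15))
  age <- pmin(90, pmax(25, rnorm(n, 62, 12)))
  baseline <- runif(n, config$baseline_egfr_range[1], config$baseline_egfr_range[2])
  followup <- runif(n, config$followup_days_range[1], config$followup_days_range[2])

  # Progressors keep their drawn slope (floored at -2/yr) and have their
  # follow-up extended past the expected eGFR-29 crossing so a 90-day stable
  # stage IV/V period is constructible. Non-progressor slopes are floored so
  # the expected trajectory stays >= 35 through follow-up (no spurious stable
  # IV/V periods from measurement noise).
  slope <- numeric(n)
  draw_p <- rnorm(n, config$slope_progressor[1], config$slope_progressor[2])
  draw_n <- rnorm(n, config$slope_nonprogressor[1], config$slope_nonprogressor[2])
  slope[progressor] <- pmin(draw_p[progressor], -2)
  floor_np <- -(baseline - 35) * 365 / followup
  slope[!progressor] <- pmax(draw_n[!progressor], floor_np[!progressor])
  # a progressor's record ends 270-450 days after the expected eGFR-29
  # crossing: long enough to establish a stable stage IV/V period, short
  # enough that the trajectory stays clear of the eGFR floor
  t_cross <- (baseline - 29) * 365 / pmax(-slope, 1e-9)
  followup[progressor] <- t_cross[progressor] +
    runif(sum(progressor), 270, 450)

  # patient-level set points for the stationary covariates
  base_hgb <- rnorm(n, 13.5, 1.2)
  base_sbp <- rnorm(n, 132, 14)
  base_dbp <- rnorm(n, 78, 9)
  base_bmi <- pmax(16, rnorm(n, 29, 5.5))
  base_alb <- rnorm(n, 4.0, 0.35)
  base_ua  <- rnorm(n, 6.0, 1.2)

  behavior_vars <- cat$variable[cat$category == "behavior"]
  p_init_beh <- c(smoking_status = 0.3, alcohol_use = 0.4, drug_use = 0.1)

  obs_list <- vector("list", n)
  for (i in seq_len(n)) {
    n_draw <- ceiling(1.5 * followup[i] / config$visit_gap_mean_days) + 20
    gaps <- 1 + rgamma(n_draw, shape = 2,
                       scale = (config$visit_gap_mean_days - 1) / 2)
    while (sum(gaps) < followup[i]) {
      gaps <- c(gaps, 1 + rgamma(20, shape = 2,
                                 scale = (config$visit_gap_mean_days - 1) / 2))
    }
    tt <- cumsum(c(0, gaps))
    tt <- tt[tt <= followup[i]]
    K <- length(tt)
    true_egfr <- pmax(baseline[i] + slope[i] * tt / 365, 5)

    egfr_obs <- pmax(true_egfr + rnorm(K, 0, config$egfr_noise_sd), 5)
    # study-entry conditioning: the first reading is observed in stage II/III
    while (egfr_obs[1] < 30 || egfr_obs[1] > 89) {
      egfr_obs[1] <- max(true_egfr[1] + rnorm(1, 0, config$egfr_noise_sd), 5)
    }

    ref <- if (config$correlated_covariates) true_egfr else rep(60, K)
    vals <- list(
      egfr        = egfr_obs,
      creatinine  = 75 / pmax(ref, 6) + rnorm(K, 0, 0.12),
      hemoglobin  = base_hgb[i] - 0.04 * pmax(60 - ref, 0) + rnorm(K, 0, 0.7),
      bicarbonate = 24 + 0.05 * (pmin(ref, 90) - 60) + rnorm(K, 0, 1.5),
      phosphorus  = 3.5 + 0.03 * pmax(60 - ref, 0) + rnorm(K, 0, 0.5),
      albumin     = base_alb[i] + rnorm(K, 0, 0.25),
      uric_acid   = base_ua[i] + rnorm(K, 0, 0.8),
      sbp         = base_sbp[i] + rnorm(K, 0, 8),
      dbp         = base_dbp[i] + rnorm(K, 0, 6),
      bmi         = base_bmi[i] + rnorm(K, 0, 0.6)
    )
    for (bv in behavior_vars) {
      vals[[bv]] <- as.numeric(markov_chain(K, p_init_beh[[bv]], 0.95))
    }
    vals <- vals[cat$variable]  # catalog order

    vlen <- length(vals)
    df <- data.frame(
      patient_id = rep(ids[i], K * vlen),
      variable = rep(cat$variable, each = K),
      t = rep(tt, vlen),
      value = unlist(vals, use.names = FALSE),
      stringsAsFactors = FALSE
    )
    keep <- runif(nrow(df)) >= config$missingness_rate
    keep[df$variable == "egfr" & df$t == 0] <- TRUE  # entry observation
    obs_list[[i]] <- df[keep, , drop = FALSE]
  }

  obs <- do.call(rbind, obs_list)
  obs <- obs[order(obs$patient_id, obs$variable, obs$t), , drop = FALSE]
  rownames(obs) <- NULL

  out <- list(
    observations = obs,
    static = data.frame(patient_id = ids, sex = sex, race = race,
                        age_at_start = age, stringsAsFactors = FALSE),
    ground_truth = data.frame(patient_id = ids, progressor = progressor,
                              stringsAsFactors = FALSE),
    config = config
  )
  class(out) <- "ckd_cohort"
  out
}

#' @export
print.ckd_cohort <- function(x, ...) {
  cat("Synthetic CKD cohort:", nrow(x$static), "patients,",
      nrow(x$observations), "observations,",
      sum(x$ground_truth$progressor), "latent progressors\n")
  invisible(x)
}

#' Generator self-validation: recover configured eGFR slopes
#'
#' Fits a per-patient ordinary least-squares line of observed eGFR on time
#' (in years) and averages the fitted slopes within the latent progressor
#' and non-progressor groups. Used to check that the generator's configured
#' decline rates are recoverable from the emitted data. Patients with fewer
#' than two eGFR readings are skipped (with a message).
#'
#' @param cohort A `ckd_cohort`.
#' @return Data frame with one row per group: `group`, `n`, `mean_slope`,
#'   `se` (standard error of the group mean).
#' @export
trajectory_slope_check <- function(cohort) {
  gt <- cohort$ground_truth
  egfr <- cohort$observations[cohort$observations$variable == "egfr", ]
  sl <- split(egfr, egfr$patient_id)
  slopes <- vapply(sl, function(d) {
    if (nrow(d) < 2) return(NA_real_)
    coef(lm(d$value ~ I(d$t / 365)))[2]
  }, numeric(1))
  n_skip <- sum(is.na(slopes))
  if (n_skip > 0)
    message(n_skip, " patient(s) with < 2 eGFR readings skipped")
  slopes <- slopes[!is.na(slopes)]
  grp <- gt$progressor[match(names(slopes), gt$patient_id)]
  out <- lapply(c(TRUE, FALSE), function(g) {
    s <- slopes[grp == g]
    if (length(s) == 0)
      stop("empty ground-truth group: ", if (g) "progressor" else "non-progressor")
    if (length(s) < 10)
      stop("need >= 10 patients per group, got ", length(s))
    data.frame(group = if (g) "progressor" else "non-progressor",
               n = length(s), mean_slope = mean(s),
               se = sd(s) / sqrt(length(s)), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
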