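#' Cross-validation plan
#'
#' Repeated random stratified ten-fold cross-validation: per trial the
#' patients are partitioned into `k` folds, `k - 2` of which train the
#' model, one validates (dropout selection / early stopping / boosting
#' rounds), and one tests. Folds are stratified by label; by default a
#' matched case-control set is kept inside one fold so that near-twin
#' controls of a test case never appear in its training data.
#'
#' @param k Number of folds (default 10).
#' @param n_trials Number of random trials (the full analysis uses 100;
#'   tests and examples use fewer).
#' @param group_by_match Keep matched sets within a fold (default TRUE;
#'   requires a `match_id` column from [match_controls()]).
#' @param seed Integer seed.
#' @return An object of class `ckd_cv_plan`.
#' @export
cv_plan <- function(k = 10, n_trials = 5, group_by_match = TRUE, seed = 1L) {
  if (k < 3) stop("k must be >= 3 (train/validation/test roles)")
  structure(list(k = as.integer(k), n_trials = as.integer(n_trials),
                 group_by_match = isTRUE(group_by_match),
                 seed = as.integer(seed)),
            class = "ckd_cv_plan")
}

# Partition units into k folds, stratified by whether the unit contains a
# case. Units are matched sets when grouping is on, single patients
# otherwise. Returns an integer fold id per row of meta.
assign_folds <- function(meta, k, group_by_match) {
  if (group_by_match && !is.null(meta$match_id)) {
    unit <- ifelse(is.na(meta$match_id), meta$patient_id, meta$match_id)
  } else {
    unit <- meta$patient_id
  }
  units <- unique(unit)
  has_case <- vapply(split(meta$label, unit)[units],
                     function(l) any(l == 1), logical(1))
  fold_of_unit <- setNames(integer(length(units)), units)
  for (stratum in list(units[has_case], units[!has_case])) {
    if (length(stratum) == 0) next
    shuffled <- stratum[order(runif(length(stratum)))]
    fold_of_unit[shuffled] <- rep_len(seq_len(k), length(shuffled))
  }
  unname(fold_of_unit[unit])
}

trial_metrics <- function(labels, scores, races) {
  out <- list(auroc = auroc(labels, scores),
              auprc = auprc(labels, scores),
              mcc = mcc(labels, scores))
  for (rc in c("African American", "white", "others")) {
    sel <- races == rc
    key <- paste0("auroc_", gsub(" ", "_", tolower(rc)))
    out[[key]] <- if (length(unique(labels[sel])) == 2)
      auroc(labels[sel], scores[sel]) else NA_real_
  }
  out
}

# Fit one model kind on one trial's folds and score the test fold.
fit_and_score <- function(kind, dataset, stats, idx_train, idx_val, idx_test,
                          t_pre, lstm_cfg) {
  meta <- dataset$meta
  sub <- function(idx) {
    d <- dataset
    d$meta <- meta[idx, , drop = FALSE]
    d$series <- dataset$series[d$meta$patient_id]
    d
  }
  if (kind == "lstm") {
    tr <- dataset_tensor(sub(idx_train), stats, lstm_cfg$max_len)
    va <- dataset_tensor(sub(idx_val), stats, lstm_cfg$max_len)
    te <- dataset_tensor(sub(idx_test), stats, lstm_cfg$max_len)
    model <- fit_lstm(tr, va, lstm_cfg)
    score_risk(model, te)
  } else if (kind == "cox_static") {
    df <- dataset_cox_static(sub(c(idx_train, idx_val)), stats, t_pre)
    model <- fit_cox_static(df, horizon = t_pre)
    te <- dataset_cox_static(sub(idx_test), stats, t_pre)
    score_risk(model, te)
  } else if (kind == "cox_dynamic") {
    df <- dataset_cox_dynamic(sub(c(idx_train, idx_val)), stats, t_pre)
    model <- fit_cox_dynamic(df, horizon = t_pre)
    snap <- dataset_snapshot(sub(idx_test), stats)
    snap <- snap[, setdiff(colnames(snap), cox_drop_cols), drop = FALSE]
    score_risk(model, as.data.frame(snap, check.names = FALSE))
  } else if (kind %in% c("random_forest", "gbdt")) {
    xtr <- dataset_snapshot(sub(idx_train), stats)
    xva <- dataset_snapshot(sub(idx_val), stats)
    xte <- dataset_snapshot(sub(idx_test), stats)
    model <- fit_snapshot_baseline(
      list(x = xtr, y = meta$label[idx_train]),
      list(x = xva, y = meta$label[idx_val]), kind)
    score_risk(model, xte)
  } else stop("unknown model kind: ", kind)
}

#' Run repeated cross-validation trials for a set of models
#'
#' Per trial: one random stratified partition into `k` folds with a single
#' train/validation/test role assignment; imputation medians and z-scoring
#' statistics are computed on the training folds only; each model is
#' trained per its protocol (the LSTM uses the validation fold for dropout
#' selection and early stopping, the Cox models and the random forest
#' merge training and validation, the gradient-boosted model uses the
#' validation fold for its boosting rounds) and scored on the test fold.
#' If the test fold ends up single-class the trial partition is redrawn
#' once, then an error is raised.
#'
#' @param dataset A matched, labeled `ckd_dataset`.
#' @param models Character vector among `"lstm"`, `"cox_static"`,
#'   `"cox_dynamic"`, `"random_forest"`, `"gbdt"`.
#' @param plan A [cv_plan()].
#' @param lstm_cfg An [lstm_config()] for the LSTM entries.
#' @return Data frame of per-trial results (one row per model x trial):
#'   `model`, `trial`, `auroc`, `auprc`, `mcc`, per-race AUROC columns,
#'   `n_test_cases`, `n_test_controls`. Class `ckd_trial_results`.
#' @export
run_trials <- function(dataset,
                       models = c("lstm", "random_forest", "gbdt",
                                  "cox_dynamic", "cox_static"),
                       plan = cv_plan(),
                       lstm_cfg = lstm_config()) {
  meta <- dataset$meta
  t_pre <- dataset$config$t_pre
  set.seed(plan$seed)
  trial_seeds <- sample.int(.Machine$integer.max - 1, plan$n_trials)

  rows <- list()
  for (trial in seq_len(plan$n_trials)) {
    set.seed(trial_seeds[trial])
    for (attempt in 1:2) {
      folds <- assign_folds(meta, plan$k, plan$group_by_match)
      roles <- sample(plan$k, 2)
      idx_test <- which(folds == roles[1])
      idx_val <- which(folds == roles[2])
      idx_train <- which(!folds %in% roles)
      if (length(unique(meta$label[idx_test])) == 2) break
      if (attempt == 2) stop("test fold with a single class after resampling")
    }
    stats <- preprocess_stats(dataset, idx_train)
    for (kind in models) {
      scores <- fit_and_score(kind, dataset, stats, idx_train, idx_val,
                              idx_test, t_pre, lstm_cfg)
      m <- trial_metrics(meta$label[idx_test], scores, meta$race[idx_test])
      rows[[length(rows) + 1]] <- data.frame(
        model = kind, trial = trial, as.data.frame(m),
        n_test_cases = sum(meta$label[idx_test] == 1),
        n_test_controls = sum(meta$label[idx_test] == 0),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("ckd_trial_results", class(out))
  out
}

#' Summarize trial results (mean and sd per metric per model)
#'
#' @param results Output of [run_trials()].
#' @return Data frame with one row per model: mean and sd of AUROC,
#'   AUPRC and MCC across trials.
#' @export
summarize_trials <- function(results) {
  sp <- split(results, results$model)
  out <- lapply(sp, function(d) {
    data.frame(model = d$model[1],
               auroc_mean = mean(d$auroc), auroc_sd = sd(d$auroc),
               auprc_mean = mean(d$auprc), auprc_sd = sd(d$auprc),
               mcc_mean = mean(d$mcc), mcc_sd = sd(d$mcc),
               n_trials = nrow(d), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Race-stratified prediction performance
#'
#' Per racial group: mean and sd of the per-trial test-fold AUROC computed
#' on that group's members, plus the maximum pairwise difference in mean
#' AUROC over the three group comparisons. Trials in which a group's test
#' members are single-class are excluded from that group's mean (their
#' count is reported).
#'
#' @param results Output of [run_trials()].
#' @return List with `table` (per model x race: mean, sd, n trials used)
#'   and `max_difference` (per model).
#' @export
race_stratified <- function(results) {
  races <- c("african_american", "white", "others")
  sp <- split(results, results$model)
  tab <- list(); maxdiff <- list()
  for (mn in names(sp)) {
    d <- sp[[mn]]
    means <- numeric(0)
    for (rc in races) {
      v <- d[[paste0("auroc_", rc)]]
      used <- sum(!is.na(v))
      tab[[length(tab) + 1]] <- data.frame(
        model = mn, race = rc,
        auroc_mean = if (used > 0) mean(v, na.rm = TRUE) else NA_real_,
        auroc_sd = if (used > 1) sd(v, na.rm = TRUE) else NA_real_,
        n_trials_used = used, n_trials_skipped = sum(is.na(v)),
        stringsAsFactors = FALSE)
      means[rc] <- if (used > 0) mean(v, na.rm = TRUE) else NA_real_
    }
    pd <- abs(c(means[1] - means[2], means[1] - means[3], means[2] - means[3]))
    maxdiff[[mn]] <- if (all(is.na(pd))) NA_real_ else max(pd, na.rm = TRUE)
  }
  list(table = do.call(rbind, tab),
       max_difference = unlist(maxdiff))
}

#' Permute dataset labels for null calibration
#'
#' Randomly permutes the case/control labels across patients, severing the
#' label-feature association while preserving the label marginal. So that
#' the survival baselines stay well-defined, a patient carrying a permuted
#' case label is assigned a pseudo transition point at the end of its
#' known span (`T_last + t_pre`). On a permuted dataset every model's
#' expected AUROC is 0.5.
#'
#' @param dataset A `ckd_dataset`.
#' @param seed Integer seed for the permutation.
#' @return The dataset with permuted labels.
#' @export
permute_labels <- function(dataset, seed = 1L) {
  set.seed(seed)
  meta <- dataset$meta
  meta$label <- sample(meta$label)
  t_pre <- dataset$config$t_pre
  meta$T_tra <- ifelse(meta$label == 1, meta$T_last + t_pre, NA_real_)
  dataset$meta <- meta
  dataset
}
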