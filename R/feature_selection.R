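#' Two-sided paired t-test between per-trial AUROC vectors
#'
#' Trial-aligned comparison of two models evaluated on the same
#' cross-validation partitions. Identical vectors (zero variance of the
#' differences) return p = 1 with a `degenerate` attribute.
#'
#' @param aurocs_a,aurocs_b Equal-length (>= 3) per-trial metric vectors.
#' @return The two-sided paired t-test p-value.
#' @export
paired_compare <- function(aurocs_a, aurocs_b) {
  if (length(aurocs_a) != length(aurocs_b))
    stop("per-trial vectors must have equal length")
  if (length(aurocs_a) < 3)
    stop("need at least 3 trials")
  d <- aurocs_a - aurocs_b
  if (sd(d) < 1e-12) {
    p <- 1
    attr(p, "degenerate") <- TRUE
    return(p)
  }
  t.test(aurocs_a, aurocs_b, paired = TRUE)$p.value
}

#' Sequential forward variable selection
#'
#' Starts from the time feature alone and adds one variable per step: at
#' each step, within each cross-validation trial, every not-yet-selected
#' variable is tried and the one maximizing the test-fold AUROC is chosen
#' for that trial (an exhaustive search over the remaining candidates).
#' Reported per step: the selection frequency of each variable across
#' trials, the modal (most frequently chosen) variable, the mean and sd of
#' the per-trial best AUROC, and a two-sided paired t-test against the
#' all-variables model on the same partitions, Benjamini-Hochberg adjusted
#' across steps.
#'
#' The per-trial selected sets grow independently (trials may disagree on
#' which variable wins a step, which is exactly what the selection
#' frequencies quantify).
#'
#' @param dataset A matched `ckd_dataset` assembled with all variables.
#' @param plan A [cv_plan()] (its seed fixes the trial partitions).
#' @param max_steps Number of selection steps (clipped with a warning at
#'   the number of candidates).
#' @param candidates Variable names to search over (default: every
#'   variable in the dataset).
#' @param lstm_cfg An [lstm_config()] used for every fit.
#' @return An object of class `ckd_selection_path`: list with `steps`
#'   (data frame: step, modal variable, mean/sd AUROC, adjusted p-value),
#'   `frequencies` (per step, named selection-frequency vectors),
#'   `per_trial` (chosen variable per trial per step),
#'   `all_variables_auroc` (per-trial reference).
#' @export
forward_select <- function(dataset, plan = cv_plan(n_trials = 10),
                           max_steps = 1,
                           candidates = names(dataset$var_map),
                           lstm_cfg = lstm_config("essential_variables")) {
  if (max_steps > length(candidates)) {
    warning("max_steps exceeds the number of candidate variables; clipped")
    max_steps <- length(candidates)
  }
  meta <- dataset$meta
  t_pre <- dataset$config$t_pre
  set.seed(plan$seed)
  trial_seeds <- sample.int(.Machine$integer.max - 1, plan$n_trials)

  chosen <- matrix(NA_character_, plan$n_trials, max_steps)
  best_auroc <- matrix(NA_real_, plan$n_trials, max_steps)
  all_auroc <- numeric(plan$n_trials)

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
    fit_subset <- function(vars) {
      ds <- subset_variables(dataset, vars)
      stats <- preprocess_stats(ds, idx_train)
      scores <- fit_and_score("lstm", ds, stats, idx_train, idx_val,
                              idx_test, t_pre, lstm_cfg)
      auroc(meta$label[idx_test], scores)
    }
    all_auroc[trial] <- fit_subset(candidates)
    selected <- character(0)
    for (step in seq_len(max_steps)) {
      remaining <- setdiff(candidates, selected)
      aucs <- vapply(remaining, function(v) fit_subset(c(selected, v)),
                     numeric(1))
      win <- remaining[which.max(aucs)]
      chosen[trial, step] <- win
      best_auroc[trial, step] <- max(aucs)
      selected <- c(selected, win)
    }
  }

  freqs <- lapply(seq_len(max_steps), function(s) {
    tb <- table(chosen[, s])
    setNames(as.numeric(tb) / plan$n_trials, names(tb))
  })
  pvals <- vapply(seq_len(max_steps), function(s)
    as.numeric(paired_compare(best_auroc[, s], all_auroc)), numeric(1))
  padj <- p.adjust(pvals, method = "BH")
  steps <- data.frame(
    step = seq_len(max_steps),
    variable = vapply(freqs, function(f) names(f)[which.max(f)], character(1)),
    mean_auroc = colMeans(best_auroc),
    sd_auroc = apply(best_auroc, 2, sd),
    p_adj = padj, stringsAsFactors = FALSE)
  structure(list(steps = steps, frequencies = freqs, per_trial = chosen,
                 per_trial_auroc = best_auroc, pvalues_raw = pvals,
                 all_variables_auroc = all_auroc),
            class = "ckd_selection_path")
}

#' @export
print.ckd_selection_path <- function(x, ...) {
  cat("Sequential forward variable selection (",
      nrow(x$per_trial), "trials )\n")
  print(x$steps, row.names = FALSE)
  invisible(x)
}
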