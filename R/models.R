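#' LSTM model configuration
#'
#' Architecture and training settings for the LSTM progression classifier:
#' a single LSTM layer followed by a stack of ReLU dense layers with
#' dropout (the same rate across dense layers — the only tuned
#' hyper-parameter, selected on the validation fold from `dropout_grid`),
#' and a 2-node softmax output. Training minimizes weighted cross-entropy
#' (control weight 1, case weight = control/case count ratio in the
#' training set) with Adam, and early-stops on validation loss.
#'
#' The `all_variables` variant uses a larger dense stack than the
#' `essential_variables` variant (fewer input features need less
#' capacity); only the architectural shape is fixed, the sizes are
#' configurable.
#'
#' @param variant `"all_variables"` or `"essential_variables"`.
#' @param lstm_units Number of LSTM units (default 64 / 32 by variant).
#' @param dense_layer_sizes Dense layer widths (default `c(64, 32, 16)` /
#'   `c(16)` by variant).
#' @param dropout_grid Candidate dropout rates; must be a subset of
#'   `c(0, 0.1, 0.2, 0.3, 0.4, 0.5, 0.7)`.
#' @param max_epochs,patience Early-stopping budget.
#' @param batch_size Minibatch size.
#' @param learning_rate Adam learning rate.
#' @param max_len Maximum sequence length accepted by the network.
#' @return An object of class `ckd_lstm_config`.
#' @export
lstm_config <- function(variant = c("all_variables", "essential_variables"),
                        lstm_units = NULL, dense_layer_sizes = NULL,
                        dropout_grid = c(0, 0.1, 0.2, 0.3, 0.4, 0.5, 0.7),
                        max_epochs = 50, patience = 5, batch_size = 64,
                        learning_rate = 1e-3, max_len = 100) {
  variant <- match.arg(variant)
  if (is.null(lstm_units))
    lstm_units <- if (variant == "all_variables") 64L else 32L
  if (is.null(dense_layer_sizes))
    dense_layer_sizes <- if (variant == "all_variables") c(64L, 32L, 16L) else 16L
  allowed <- c(0, 0.1, 0.2, 0.3, 0.4, 0.5, 0.7)
  if (!all(dropout_grid %in% allowed))
    stop("dropout_grid must be a subset of {0, 0.1, 0.2, 0.3, 0.4, 0.5, 0.7}")
  if (any(dense_layer_sizes < 1)) stop("dense layer sizes must be positive")
  structure(list(variant = variant, lstm_units = as.integer(lstm_units),
                 dense_layer_sizes = as.integer(dense_layer_sizes),
                 dropout_grid = dropout_grid, max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, max_len = as.integer(max_len)),
            class = "ckd_lstm_config")
}

#' Class weights for weighted cross-entropy
#'
#' Control weight is 1; case weight is the control-to-case sample size
#' ratio in the training set, so both classes contribute equally to the
#' loss despite the imbalance.
#'
#' @param labels Training labels (0/1).
#' @return List with `control_weight` (1) and `case_weight`.
#' @export
class_weights <- function(labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("training set must contain both classes")
  list(control_weight = 1, case_weight = n0 / n1)
}

# --- training-fold preprocessing -------------------------------------------

#' Training-fold preprocessing statistics
#'
#' Per-feature fallback medians (for imputation) and means/sds (for
#' z-scoring), computed from training patients only so that no information
#' leaks from validation or test folds.
#'
#' @param dataset A `ckd_dataset`.
#' @param idx Row indices of the training patients in `dataset$meta`.
#' @return List with `medians`, `center`, `scale`.
#' @export
preprocess_stats <- function(dataset, idx = seq_len(nrow(dataset$meta))) {
  med <- training_medians(dataset, idx)
  mats <- lapply(dataset$series[dataset$meta$patient_id[idx]],
                 function(s) impute_series(s, med)$matrix)
  big <- do.call(rbind, mats)
  ctr <- colMeans(big)
  scl <- apply(big, 2, sd)
  scl[!is.finite(scl) | scl < 1e-8] <- 1
  list(medians = med, center = ctr, scale = scl)
}

# impute + z-score one series matrix
prepared_matrix <- function(series, stats) {
  m <- impute_series(series, stats$medians)$matrix
  sweep(sweep(m, 2, stats$center, "-"), 2, stats$scale, "/")
}

#' Build the padded sequence tensor for the LSTM
#'
#' Imputes and z-scores every series with training-fold statistics and
#' packs them right-aligned (pre-padded with zeros) into a
#' `max_len x D x N` array with a vector of true lengths.
#'
#' @param dataset A `ckd_dataset`.
#' @param stats Output of [preprocess_stats()] on the training fold.
#' @param max_len Padded length (must be >= every sequence length).
#' @return List with `X` (array), `len`, `y`, `meta`.
#' @export
dataset_tensor <- function(dataset, stats, max_len = 100) {
  meta <- dataset$meta
  n <- nrow(meta)
  if (any(meta$seq_len > max_len))
    stop("sequence longer than max_len")
  D <- length(stats$center)
  X <- array(0, dim = c(max_len, D, n))
  for (i in seq_len(n)) {
    m <- prepared_matrix(dataset$series[[meta$patient_id[i]]], stats)
    L <- nrow(m)
    X[(max_len - L + 1):max_len, , i] <- m
  }
  list(X = X, len = meta$seq_len, y = meta$label, meta = meta)
}

# snapshot (latest feature vector) design matrix
dataset_snapshot <- function(dataset, stats) {
  meta <- dataset$meta
  rows <- t(vapply(meta$patient_id, function(id) {
    m <- prepared_matrix(dataset$series[[id]], stats)
    m[nrow(m), ]
  }, numeric(length(stats$center))))
  rownames(rows) <- meta$patient_id
  rows
}

cox_drop_cols <- c("time")  # the grid-time feature is the time axis itself

# survival frame for the static Cox model: covariates at the first time
# point; cases observe the event at T_tra - T_1, controls are censored at
# T_last + t_pre - T_1 (the end of the span they are known progression-free)
dataset_cox_static <- function(dataset, stats, t_pre) {
  meta <- dataset$meta
  covs <- t(vapply(meta$patient_id, function(id) {
    m <- prepared_matrix(dataset$series[[id]], stats)
    m[1, ]
  }, numeric(length(stats$center))))
  covs <- covs[, setdiff(colnames(covs), cox_drop_cols), drop = FALSE]
  T1 <- vapply(dataset$series[meta$patient_id],
               function(s) s$grid_times[1], numeric(1))
  time <- ifelse(meta$label == 1, meta$T_tra - T1,
                 meta$T_last + t_pre - T1)
  data.frame(time = time, event = meta$label, covs, check.names = FALSE)
}

# counting-process rows for the dynamic Cox model: one row per grid
# interval, contiguous, the final row extended to the event/censoring time
dataset_cox_dynamic <- function(dataset, stats, t_pre) {
  meta <- dataset$meta
  frames <- lapply(seq_len(nrow(meta)), function(i) {
    id <- meta$patient_id[i]
    m <- prepared_matrix(dataset$series[[id]], stats)
    m <- m[, setdiff(colnames(m), cox_drop_cols), drop = FALSE]
    gt <- dataset$series[[id]]$grid_times
    n <- length(gt)
    t_end <- if (meta$label[i] == 1) meta$T_tra[i] else meta$T_last[i] + t_pre
    start <- gt
    stop_ <- c(gt[-1], t_end)
    event <- c(rep(0L, n - 1), meta$label[i])
    data.frame(patient_id = id, start = start, stop = stop_, event = event,
               m, check.names = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, frames)
  rownames(out) <- NULL
  out
}

# --- LSTM -------------------------------------------------------------------

#' Train the LSTM progression classifier
#'
#' For each dropout rate on the configured grid, trains the network with
#' weighted cross-entropy and validation-loss early stopping, then keeps
#' the model with the lowest validation loss. All randomness flows through
#' R's RNG, so `set.seed()` before the call makes training reproducible.
#'
#' @param train,val Tensors from [dataset_tensor()]; `val` drives dropout
#'   selection and early stopping and must be disjoint from `train`.
#' @param config An [lstm_config()].
#' @return An object of class `ckd_lstm` exposing [score_risk()].
#' @export
fit_lstm <- function(train, val, config = lstm_config()) {
  if (length(unique(train$y)) < 2)
    stop("training set must contain both classes")
  cw <- class_weights(train$y)$case_weight
  best <- NULL
  for (dr in config$dropout_grid) {
    fit <- lstm_train_cpp(train$X, train$len, train$y,
                          val$X, val$len, val$y,
                          config$lstm_units, config$dense_layer_sizes,
                          dr, cw, config$max_epochs, config$patience,
                          config$batch_size, config$learning_rate)
    if (is.null(best) ||
        (!is.na(fit$best_val_loss) && fit$best_val_loss < best$best_val_loss)) {
      best <- fit
      best$dropout <- dr
    }
  }
  structure(list(kind = "lstm", weights = best$weights,
                 selected_dropout = best$dropout,
                 best_val_loss = best$best_val_loss,
                 epochs_run = best$epochs_run, best_epoch = best$best_epoch,
                 config = config),
            class = "ckd_lstm")
}

#' Class probabilities from a trained LSTM
#'
#' @param object A `ckd_lstm`.
#' @param newdata A tensor from [dataset_tensor()].
#' @param ... Unused.
#' @return N x 2 matrix of class probabilities (control, case); rows sum
#'   to 1.
#' @export
predict.ckd_lstm <- function(object, newdata, ...) {
  lstm_predict_cpp(object$weights, newdata$X, newdata$len,
                   object$config$lstm_units, object$config$dense_layer_sizes)
}

# --- Cox models -------------------------------------------------------------

drop_constant_columns <- function(df, protect = c("time", "event", "start",
                                                  "stop", "patient_id")) {
  check <- setdiff(names(df), protect)
  const <- check[vapply(df[check], function(x) length(unique(x)) <= 1, logical(1))]
  if (length(const) > 0) {
    message("dropping constant covariate column(s): ",
            paste(const, collapse = ", "))
    df <- df[setdiff(names(df), const)]
  }
  df
}

cox_cumhaz_at <- function(fit, horizon) {
  bh <- survival::basehaz(fit, centered = FALSE)
  idx <- findInterval(horizon, bh$time)
  H0 <- if (idx == 0) 0 else bh$hazard[idx]
  if (H0 <= 0) {
    # horizon precedes the first training event: every predicted risk would
    # be exactly 0; fall back to the earliest positive baseline hazard so
    # scores stay monotone in the linear predictor
    pos <- bh$hazard[bh$hazard > 0]
    if (length(pos) > 0) {
      message("no baseline hazard mass before the horizon; ",
              "using the earliest event hazard")
      H0 <- min(pos)
    }
  }
  H0
}

#' Fit the static Cox proportional hazards baseline
#'
#' Uses each patient's covariates at the first time point; cases
#' contribute the event at the transition, controls are censored at the
#' end of their known progression-free span. Constant covariate columns
#' are dropped with a message. The progression risk score is
#' `1 - S(horizon)` from the Breslow baseline-hazard estimate.
#'
#' @param trainval Survival frame (internal layout; produced by the
#'   evaluation harness or the internal counting-time builders).
#' @param horizon Evaluation horizon in days for `1 - S(horizon)`.
#' @return An object of class `ckd_cox` (static flavor).
#' @export
fit_cox_static <- function(trainval, horizon = 365) {
  if (sum(trainval$event) == 0) stop("no events in the training data")
  df <- drop_constant_columns(trainval)
  covars <- setdiff(names(df), c("time", "event"))
  if (length(covars) == 0) stop("no usable covariates")
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(sprintf("`%s`", covars), collapse = " + ")))
  fit <- survival::coxph(fml, data = df)
  if (any(!is.finite(coef(fit))))
    stop("static Cox fit did not converge: non-finite coefficients")
  structure(list(kind = "cox_static", fit = fit, covars = covars,
                 horizon = horizon, H0 = cox_cumhaz_at(fit, horizon)),
            class = "ckd_cox")
}

#' Fit the dynamic Cox proportional hazards baseline
#'
#' Counting-process layout: each patient contributes one row per grid
#' interval with the covariate values of that interval; demographic
#' columns are constant across a patient's rows (time-independent) while
#' the clinical variables vary (time-dependent). The event sits on a
#' case's final row. Prediction evaluates `1 - S(horizon)` at the
#' patient's last observed covariate vector.
#'
#' @param trainval Counting-process frame (internal layout; produced by
#'   the evaluation harness or the internal counting-process builders).
#' @param horizon Evaluation horizon in days.
#' @return An object of class `ckd_cox` (dynamic flavor).
#' @export
fit_cox_dynamic <- function(trainval, horizon = 365) {
  if (sum(trainval$event) == 0) stop("no events in the training data")
  # overlapping intervals within a patient are a layout error
  by_pat <- split(trainval, trainval$patient_id)
  ok <- vapply(by_pat, function(d) {
    d <- d[order(d$start), ]
    all(d$stop > d$start) && all(d$start[-1] >= d$stop[-nrow(d)] - 1e-9)
  }, logical(1))
  if (!all(ok))
    stop("overlapping counting-process intervals for patient(s): ",
         paste(names(by_pat)[!ok], collapse = ", "))
  df <- drop_constant_columns(trainval)
  covars <- setdiff(names(df), c("patient_id", "start", "stop", "event"))
  if (length(covars) == 0) stop("no usable covariates")
  fml <- stats::as.formula(paste("survival::Surv(start, stop, event) ~",
                                 paste(sprintf("`%s`", covars), collapse = " + ")))
  fit <- survival::coxph(fml, data = df)
  if (any(!is.finite(coef(fit))))
    stop("dynamic Cox fit did not converge: non-finite coefficients")
  structure(list(kind = "cox_dynamic", fit = fit, covars = covars,
                 horizon = horizon, H0 = cox_cumhaz_at(fit, horizon)),
            class = "ckd_cox")
}

#' Progression risk from a Cox model
#'
#' @param object A `ckd_cox`.
#' @param newdata Data frame (or matrix) of covariates — for the dynamic
#'   flavor, the last observed covariate vector per patient.
#' @param ... Unused.
#' @return Numeric vector of `1 - S(horizon)` risks in \[0, 1\].
#' @export
predict.ckd_cox <- function(object, newdata, ...) {
  Xm <- as.matrix(newdata[, object$covars, drop = FALSE])
  lp <- drop(Xm %*% coef(object$fit))
  1 - exp(-object$H0 * exp(lp))
}

# --- snapshot baselines -----------------------------------------------------

#' Fit a snapshot ensemble baseline (random forest or gradient boosting)
#'
#' Both baselines are trained on each patient's latest feature vector
#' (time feature included). The random forest merges training and
#' validation sets (no tuning needed); the gradient-boosted model
#' (xgboost) uses the validation fold to early-stop the boosting rounds.
#'
#' @param train,val Lists with `x` (matrix) and `y` (0/1) as produced by
#'   the evaluation harness.
#' @param kind `"random_forest"` or `"gbdt"`.
#' @param ntree Trees for the random forest.
#' @param nrounds Maximum boosting rounds for the gradient-boosted model.
#' @return An object of class `ckd_snapshot`.
#' @export
fit_snapshot_baseline <- function(train, val = NULL,
                                  kind = c("random_forest", "gbdt"),
                                  ntree = 500, nrounds = 300) {
  kind <- match.arg(kind)
  if (length(unique(train$y)) < 2)
    stop("training set must contain both classes")
  if (kind == "random_forest") {
    x <- train$x; y <- train$y
    if (!is.null(val)) {  # merge train + validation
      x <- rbind(x, val$x); y <- c(y, val$y)
    }
    fit <- randomForest::randomForest(x = x, y = factor(y, levels = c(0, 1)),
                                      ntree = ntree)
    structure(list(kind = "random_forest", fit = fit), class = "ckd_snapshot")
  } else {
    dtrain <- xgboost::xgb.DMatrix(train$x, label = train$y)
    params <- list(objective = "binary:logistic", eta = 0.1, max_depth = 3,
                   nthread = 1)
    if (!is.null(val)) {
      dval <- xgboost::xgb.DMatrix(val$x, label = val$y)
      fit <- xgboost::xgb.train(params, dtrain, nrounds = nrounds,
                                evals = list(val = dval),
                                early_stopping_rounds = 20, verbose = 0)
    } else {
      fit <- xgboost::xgb.train(params, dtrain, nrounds = nrounds, verbose = 0)
    }
    structure(list(kind = "gbdt", fit = fit), class = "ckd_snapshot")
  }
}

#' @export
predict.ckd_snapshot <- function(object, newdata, ...) {
  if (object$kind == "random_forest") {
    unname(predict(object$fit, newdata, type = "prob")[, "1"])
  } else {
    unname(predict(object$fit, xgboost::xgb.DMatrix(newdata)))
  }
}

#' Progression risk score under the common model contract
#'
#' Every model kind exposes the same contract: a score in \[0, 1\], higher
#' meaning higher predicted risk of progression to stages IV/V.
#'
#' @param model A fitted `ckd_lstm`, `ckd_cox` or `ckd_snapshot`.
#' @param newdata The model's prediction input (tensor, covariate frame or
#'   snapshot matrix).
#' @return Numeric vector of risk scores.
#' @export
score_risk <- function(model, newdata) {
  if (inherits(model, "ckd_lstm")) return(predict(model, newdata)[, 2])
  predict(model, newdata)
}
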