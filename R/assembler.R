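#' Configuration for time-series assembly
#'
#' Controls how a patient's irregular observations are converted into a
#' fixed-interval sequence of feature vectors and how case/control windows
#' are applied.
#'
#' @param t_w Interval width in days (default 7). Intervals are half-open
#'   `[k t_w, (k+1) t_w)` anchored at `t = 0` (record start); the n-th
#'   feature vector is stamped with the interval midpoint
#'   `T_n = (n - 0.5) t_w`, which is also appended as the time feature.
#' @param t_gap Gap period in days between the last usable feature vector
#'   and the prediction window (default 7); prevents label leakage from
#'   measurements taken at (or effectively defining) the transition.
#' @param t_pre Prediction window in days (typically 90, 365, 1095 or
#'   1825): a case's transition must fall within `t_pre` of its last used
#'   time point; a control's final `t_pre` span of feature vectors is
#'   removed.
#' @param max_len Maximum sequence length; only the latest `max_len` time
#'   points are used (default 100).
#' @param min_case_len Minimum number of time points a patient must retain
#'   after windowing (default 5).
#' @param variable_set `"all"` or `"essential"` (the essential subset of
#'   the variable catalog).
#' @param exclude_IIIb If `TRUE`, each patient's observation stream is
#'   truncated at the first eGFR reading at or below 44 (start of
#'   stage-IIIb-or-worse information) before assembly, emulating prediction
#'   from stages II/IIIa only. Case status and the transition point are
#'   still determined from the full eGFR series; only window validity is
#'   re-evaluated on the truncated stream.
#' @return An object of class `ckd_assembly_config`.
#' @export
assembly_config <- function(t_w = 7, t_gap = 7, t_pre = 365, max_len = 100,
                            min_case_len = 5, variable_set = c("all", "essential"),
                            exclude_IIIb = FALSE) {
  variable_set <- match.arg(variable_set)
  if (any(c(t_w, t_gap, t_pre) <= 0)) stop("t_w, t_gap, t_pre must be > 0")
  if (max_len < 1 || min_case_len < 1) stop("max_len and min_case_len must be >= 1")
  structure(list(t_w = t_w, t_gap = t_gap, t_pre = t_pre, max_len = max_len,
                 min_case_len = min_case_len, variable_set = variable_set,
                 exclude_IIIb = isTRUE(exclude_IIIb)),
            class = "ckd_assembly_config")
}

# Feature column layout for a given catalog + variable set.
# Returns list(cols = column names, var_map = variable -> column names).
feature_layout <- function(catalog, variable_set = "all") {
  vars <- catalog$variable
  if (variable_set == "essential") vars <- vars[catalog$essential]
  var_map <- as.list(setNames(vars, vars))
  var_map$sex <- "sex"
  var_map$race <- c("race_african_american", "race_white")
  cols <- c("time", vars, "sex", "race_african_american", "race_white")
  list(cols = cols, var_map = var_map, timevarying = vars)
}

#' Bin one patient's observations into a feature-vector series
#'
#' Aggregates a patient's long-format observations onto a uniform grid of
#' `t_w`-day half-open intervals anchored at `t = 0`: lab and vital values
#' falling in the same interval are arithmetic-averaged, behavior variables
#' take the latest reading in the interval, demographics (sex, race dummy
#' codes) are constant columns, and the interval midpoint is appended as
#' the time feature. Intervals with no reading of a variable are marked
#' missing (NA, with a logical mask kept for audit); empty intervals
#' between observed ones are kept as grid rows so the time step stays
#' uniform.
#'
#' @param obs One patient's rows of the long observation table
#'   (`variable`, `t`, `value`), time-sorted.
#' @param static_row One-row data frame with `sex`, `race`.
#' @param config An [assembly_config()].
#' @param catalog Variable catalog (see [default_variable_catalog()]).
#' @return An object of class `ckd_series`: list with `grid_times`
#'   (interval midpoints in days), `matrix` (N x D, NA = missing),
#'   `mask` (N x D logical, TRUE = observed), `var_map`.
#' @export
bin_observations <- function(obs, static_row, config = assembly_config(),
                             catalog = default_variable_catalog()) {
  lay <- feature_layout(catalog, config$variable_set)
  unknown <- setdiff(unique(obs$variable), catalog$variable)
  if (length(unknown) > 0)
    stop("unknown variable(s) in observations: ", paste(unknown, collapse = ", "))
  obs <- obs[obs$variable %in% lay$timevarying, , drop = FALSE]
  if (nrow(obs) == 0) stop("no observations for the configured variable set")
  t_w <- config$t_w
  idx <- floor(obs$t / t_w) + 1L
  N <- max(idx)
  grid_times <- (seq_len(N) - 0.5) * t_w

  mat <- matrix(NA_real_, N, length(lay$cols), dimnames = list(NULL, lay$cols))
  mat[, "time"] <- grid_times
  behavior <- catalog$variable[catalog$category == "behavior"]
  for (v in lay$timevarying) {
    sel <- obs$variable == v
    if (!any(sel)) next
    ti <- idx[sel]; va <- obs$value[sel]; tt <- obs$t[sel]
    if (v %in% behavior) {
      # latest reading in each interval
      o <- order(ti, tt)
      ti <- ti[o]; va <- va[o]
      last <- !duplicated(ti, fromLast = TRUE)
      mat[ti[last], v] <- va[last]
    } else {
      agg <- tapply(va, ti, mean)
      mat[as.integer(names(agg)), v] <- agg
    }
  }
  mat[, "sex"] <- as.numeric(static_row$sex == "male")
  mat[, "race_african_american"] <- as.numeric(static_row$race == "African American")
  mat[, "race_white"] <- as.numeric(static_row$race == "white")

  mask <- !is.na(mat)
  structure(list(grid_times = grid_times, matrix = mat, mask = mask,
                 var_map = lay$var_map),
            class = "ckd_series")
}

series_subset_rows <- function(series, keep) {
  series$grid_times <- series$grid_times[keep]
  series$matrix <- series$matrix[keep, , drop = FALSE]
  series$mask <- series$mask[keep, , drop = FALSE]
  series
}

#' Impute missing entries of a feature-vector series
#'
#' Per variable: last-observation-carried-forward, then
#' next-observation-carried-backward, then the training-population median.
#' Observed entries are never altered; the pre-imputation mask on the
#' series is preserved for audit.
#'
#' @param series A `ckd_series` (or a bare numeric matrix with named
#'   columns).
#' @param training_stats Named numeric vector of per-column fallback
#'   medians, computed from training patients only (see
#'   [training_medians()]).
#' @return The series (or matrix) with no missing entries.
#' @export
impute_series <- function(series, training_stats) {
  mat <- if (inherits(series, "ckd_series")) series$matrix else series
  missing_cols <- setdiff(colnames(mat), names(training_stats))
  if (length(missing_cols) > 0)
    stop("no training statistics for variable(s): ",
         paste(missing_cols, collapse = ", "))
  for (j in seq_len(ncol(mat))) {
    x <- mat[, j]
    if (!anyNA(x)) next
    obs <- which(!is.na(x))
    if (length(obs) > 0) {
      # LOCF
      filled <- cummax(ifelse(is.na(x), 0L, seq_along(x)))
      x[filled > 0] <- x[obs][findInterval(which(filled > 0), obs)]
      # NOCB for the leading run
      if (is.na(x[1])) x[seq_len(obs[1] - 1)] <- x[obs[1]]
    } else {
      x[] <- training_stats[[colnames(mat)[j]]]
    }
    mat[, j] <- x
  }
  if (inherits(series, "ckd_series")) {
    series$matrix <- mat
    series
  } else mat
}

#' Apply the case window to a series
#'
#' Drops every time point with midpoint `T_n >= T_tra - t_gap` and checks
#' case validity: at least `min_case_len` time points must remain and the
#' transition must fall inside the prediction window measured from the last
#' used time point, `t_gap <= T_tra - T_last <= t_pre`.
#'
#' @param series A `ckd_series`.
#' @param T_tra Transition point in days.
#' @param config An [assembly_config()].
#' @return List with `series` (trimmed), `valid` (flag), `reason`
#'   (`NA` if valid; `"too_short"` or `"transition_outside_window"`).
#' @export
apply_case_window <- function(series, T_tra, config = assembly_config()) {
  keep <- series$grid_times < T_tra - config$t_gap
  trimmed <- series_subset_rows(series, keep)
  n <- length(trimmed$grid_times)
  if (n < config$min_case_len)
    return(list(series = trimmed, valid = FALSE, reason = "too_short"))
  T_last <- trimmed$grid_times[n]
  gap <- T_tra - T_last
  if (gap < config$t_gap || gap > config$t_pre)
    return(list(series = trimmed, valid = FALSE,
                reason = "transition_outside_window"))
  list(series = trimmed, valid = TRUE, reason = NA_character_)
}

#' Apply the control truncation to a series
#'
#' Removes the latest feature vectors spanning a period of `t_pre`: every
#' time point with midpoint `T_n > T_end - t_pre` is dropped, where `T_end`
#' is the last grid midpoint carrying any observed (non-demographic)
#' value. The retained prefix is known progression-free for at least
#' `t_pre` days. The control stays eligible only if at least
#' `min_case_len` time points remain.
#'
#' @param series A `ckd_series`.
#' @param config An [assembly_config()].
#' @return List with `series`, `valid`, `reason`.
#' @export
apply_control_truncation <- function(series, config = assembly_config()) {
  tv_cols <- setdiff(colnames(series$matrix),
                     c("time", "sex", "race_african_american", "race_white"))
  has_obs <- rowSums(series$mask[, tv_cols, drop = FALSE]) > 0
  if (!any(has_obs))
    return(list(series = series_subset_rows(series, rep(FALSE, length(series$grid_times))),
                valid = FALSE, reason = "too_short"))
  T_end <- series$grid_times[max(which(has_obs))]
  keep <- series$grid_times <= T_end - config$t_pre
  trimmed <- series_subset_rows(series, keep)
  if (length(trimmed$grid_times) < config$min_case_len)
    return(list(series = trimmed, valid = FALSE, reason = "too_short"))
  list(series = trimmed, valid = TRUE, reason = NA_character_)
}

#' Keep only the latest time points of a series
#'
#' @param series A `ckd_series`.
#' @param max_len Maximum number of time points retained.
#' @return The series with at most `max_len` (latest) time points.
#' @export
truncate_length <- function(series, max_len = 100) {
  n <- length(series$grid_times)
  if (n <= max_len) return(series)
  series_subset_rows(series, seq_len(n) > n - max_len)
}

#' Truncate an observation stream at the first stage-IIIb eGFR reading
#'
#' Removes all of a patient's observations (all variables) from the time
#' of the first eGFR reading at or below 44 onward, leaving only the
#' patient's stage II/IIIa history for feature construction.
#'
#' @param obs One patient's long-format observation rows.
#' @param threshold eGFR threshold (default 44, the upper IIIb bound).
#' @return The filtered observation rows.
#' @export
exclude_stage_IIIb <- function(obs, threshold = 44) {
  egfr <- obs[obs$variable == "egfr", ]
  egfr <- egfr[order(egfr$t), ]
  hit <- which(egfr$value <= threshold)
  if (length(hit) == 0) return(obs)
  t_cut <- egfr$t[hit[1]]
  obs[obs$t < t_cut, , drop = FALSE]
}

#' Assemble the labeled modeling dataset
#'
#' Runs the full per-patient assembly: optional stage-IIIb stream
#' truncation, interval binning, the case window or control truncation,
#' and length truncation; attaches the binary progression label (1 = valid
#' case, 0 = retained control) and the matching keys (race, sex, age at the
#' last used time point, sequence length). Patients invalidated by the
#' windowing rules are dropped and recorded in the `drop_log` attribute.
#' Missing entries are left as NA (with masks): imputation and
#' standardization are training-fold operations performed at modeling time.
#'
#' @param cohort A `ckd_cohort`.
#' @param assignments Cohort table from [build_cohort()].
#' @param config An [assembly_config()].
#' @return An object of class `ckd_dataset`: list with `meta` (data frame:
#'   `patient_id`, `label`, `seq_len`, `race`, `sex`, `age`, `T_last`,
#'   `T_tra`), `series` (list of `ckd_series`), `config`, `var_map`.
#' @export
assemble_dataset <- function(cohort, assignments, config = assembly_config()) {
  catalog <- if (!is.null(cohort$config)) cohort$config$variable_catalog
             else default_variable_catalog()
  keep <- assignments$status %in% c("case", "control")
  assignments <- assignments[keep, , drop = FALSE]
  obs_all <- cohort$observations[cohort$observations$patient_id %in%
                                   assignments$patient_id, , drop = FALSE]
  obs_split <- split(obs_all, obs_all$patient_id)
  static <- cohort$static

  meta_rows <- list(); series_list <- list(); drop_log <- list()
  var_map <- NULL
  for (r in seq_len(nrow(assignments))) {
    id <- assignments$patient_id[r]
    is_case <- assignments$status[r] == "case"
    obs <- obs_split[[id]]
    if (is.null(obs)) next
    if (config$exclude_IIIb) {
      obs <- exclude_stage_IIIb(obs)
      if (nrow(obs) == 0 || !any(obs$variable == "egfr")) {
        drop_log[[id]] <- "no_pre_IIIb_history"
        next
      }
    }
    st <- static[static$patient_id == id, , drop = FALSE]
    series <- bin_observations(obs, st, config, catalog)
    if (is.null(var_map)) var_map <- series$var_map
    w <- if (is_case) apply_case_window(series, assignments$T_tra[r], config)
         else apply_control_truncation(series, config)
    if (!w$valid) {
      drop_log[[id]] <- w$reason
      next
    }
    s <- truncate_length(w$series, config$max_len)
    n <- length(s$grid_times)
    T_last <- s$grid_times[n]
    meta_rows[[id]] <- data.frame(
      patient_id = id, label = as.integer(is_case), seq_len = n,
      race = st$race, sex = st$sex,
      age = st$age_at_start + T_last / 365.25,
      T_last = T_last, T_tra = assignments$T_tra[r],
      stringsAsFactors = FALSE)
    series_list[[id]] <- s
  }
  meta <- do.call(rbind, meta_rows)
  rownames(meta) <- NULL
  out <- structure(list(meta = meta, series = series_list, config = config,
                        var_map = var_map),
                   class = "ckd_dataset")
  attr(out, "drop_log") <- unlist(drop_log)
  out
}

#' @export
print.ckd_dataset <- function(x, ...) {
  cat("CKD modeling dataset:", nrow(x$meta), "patients (",
      sum(x$meta$label == 1), "cases /", sum(x$meta$label == 0),
      "controls ),", ncol(x$series[[1]]$matrix), "feature columns\n")
  invisible(x)
}

#' Restrict a dataset to a subset of variables
#'
#' Keeps the time feature plus the named variables (catalog names or
#' `"sex"` / `"race"`, which map to their dummy columns). Used by the
#' eGFR-only analyses and by sequential forward selection.
#'
#' @param dataset A `ckd_dataset`.
#' @param vars Character vector of variable names.
#' @return The dataset with reduced feature columns.
#' @export
subset_variables <- function(dataset, vars) {
  unknown <- setdiff(vars, names(dataset$var_map))
  if (length(unknown) > 0)
    stop("unknown variable(s): ", paste(unknown, collapse = ", "))
  cols <- c("time", unlist(dataset$var_map[vars], use.names = FALSE))
  dataset$series <- lapply(dataset$series, function(s) {
    s$matrix <- s$matrix[, cols, drop = FALSE]
    s$mask <- s$mask[, cols, drop = FALSE]
    s$var_map <- dataset$var_map[vars]
    s
  })
  dataset$var_map <- dataset$var_map[vars]
  dataset
}

#' Per-column medians from training patients
#'
#' Computes the fallback median of each feature column over the observed
#' (pre-imputation) entries of the given training samples.
#'
#' @param dataset A `ckd_dataset`.
#' @param idx Indices (into `dataset$meta`) of the training patients.
#' @return Named numeric vector of medians (0 for columns never observed).
#' @export
training_medians <- function(dataset, idx = seq_len(nrow(dataset$meta))) {
  mats <- lapply(dataset$series[dataset$meta$patient_id[idx]],
                 function(s) s$matrix)
  big <- do.call(rbind, mats)
  med <- apply(big, 2, median, na.rm = TRUE)
  med[is.na(med)] <- 0
  med
}
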