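#' Case-control matching specification
#'
#' @param ratio Controls matched per case (default 4).
#' @param age_tol Maximum |age difference| in years for a control to be
#'   eligible (default 5).
#' @param seed Integer seed fixing the randomized case order.
#' @return An object of class `ckd_match_spec`.
#' @export
match_spec <- function(ratio = 4, age_tol = 5, seed = 1L) {
  if (ratio < 1) stop("ratio must be >= 1")
  if (age_tol < 0) stop("age_tol must be >= 0")
  structure(list(ratio = as.integer(ratio), age_tol = age_tol,
                 seed = as.integer(seed)),
            class = "ckd_match_spec")
}

#' Match cases with controls on race, sex, age, and sequence length
#'
#' Greedy, randomized-order, without-replacement matching: cases are
#' visited in a seeded random order; for each case the eligible controls —
#' equal race, sex and sequence length, and |age difference| at most
#' `age_tol` years — are ranked by age gap (ties broken by patient id) and
#' up to `ratio` of them are taken and removed from the pool. Cases that
#' attract zero controls are retained (dropping them would bias the
#' dataset toward easy strata) and flagged in the diagnostics.
#'
#' @param dataset A `ckd_dataset` containing both cases and controls
#'   (controls already window-truncated).
#' @param spec A [match_spec()].
#' @return A `ckd_dataset` restricted to the cases and their matched
#'   controls, with attributes `match_table` (data frame `case_id`,
#'   `control_id`, `age_gap`) and `match_diagnostics` (per-case achieved
#'   ratio and mean age gap).
#' @export
match_controls <- function(dataset, spec = match_spec()) {
  meta <- dataset$meta
  if (anyDuplicated(meta$patient_id))
    stop("duplicate patient ids across the case and control pools")
  cases <- meta[meta$label == 1, , drop = FALSE]
  controls <- meta[meta$label == 0, , drop = FALSE]
  if (nrow(cases) == 0) stop("no cases to match")

  set.seed(spec$seed)
  # shuffle a sorted id list so the order is invariant to input row order
  ids_sorted <- sort(cases$patient_id)
  case_order <- ids_sorted[order(runif(length(ids_sorted)))]
  available <- rep(TRUE, nrow(controls))
  names(available) <- controls$patient_id

  pairs <- list(); diag_rows <- list()
  for (cid in case_order) {
    cs <- cases[cases$patient_id == cid, ]
    elig <- which(available &
                    controls$race == cs$race &
                    controls$sex == cs$sex &
                    controls$seq_len == cs$seq_len &
                    abs(controls$age - cs$age) <= spec$age_tol)
    if (length(elig) > 0) {
      gap <- abs(controls$age[elig] - cs$age)
      o <- order(gap, controls$patient_id[elig])
      take <- elig[o][seq_len(min(spec$ratio, length(elig)))]
      available[take] <- FALSE
      pairs[[cid]] <- data.frame(case_id = cid,
                                 control_id = controls$patient_id[take],
                                 age_gap = abs(controls$age[take] - cs$age),
                                 stringsAsFactors = FALSE)
    }
    k <- if (is.null(pairs[[cid]])) 0L else nrow(pairs[[cid]])
    diag_rows[[cid]] <- data.frame(
      case_id = cid, achieved_ratio = k,
      mean_age_gap = if (k > 0) mean(pairs[[cid]]$age_gap) else NA_real_,
      stringsAsFactors = FALSE)
  }
  match_table <- if (length(pairs) > 0) do.call(rbind, pairs) else
    data.frame(case_id = character(), control_id = character(),
               age_gap = numeric(), stringsAsFactors = FALSE)
  rownames(match_table) <- NULL
  diagnostics <- do.call(rbind, diag_rows)
  rownames(diagnostics) <- NULL

  keep_ids <- c(cases$patient_id, match_table$control_id)
  out <- dataset
  sel <- meta$patient_id %in% keep_ids
  out$meta <- meta[sel, , drop = FALSE]
  rownames(out$meta) <- NULL
  out$series <- dataset$series[out$meta$patient_id]
  # matched-set id: each case and its controls share a group for CV folding
  grp <- setNames(match_table$case_id, match_table$control_id)
  out$meta$match_id <- ifelse(out$meta$label == 1, out$meta$patient_id,
                              grp[out$meta$patient_id])
  attr(out, "match_table") <- match_table
  attr(out, "match_diagnostics") <- diagnostics
  out
}
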