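#' Write a synthetic cohort to plain-text CSV files
#'
#' Writes `observations.csv` (columns `patient_id`, `variable`, `t_days`,
#' `value`), `static.csv` (per-patient demographics) and
#' `ground_truth.csv` (the generator's latent progressor flag — never read
#' by the pipeline). Deterministic: the same cohort writes byte-identical
#' files.
#'
#' @param cohort A `ckd_cohort`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  obs <- cohort$observations
  names(obs)[names(obs) == "t"] <- "t_days"
  write.csv(obs, file.path(dir, "observations.csv"), row.names = FALSE)
  write.csv(cohort$static, file.path(dir, "static.csv"), row.names = FALSE)
  write.csv(cohort$ground_truth, file.path(dir, "ground_truth.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort_csv()]
#'
#' @param dir Directory containing `observations.csv` and `static.csv`.
#' @return A `ckd_cohort` (without ground truth, which the pipeline never
#'   consumes; `config` carries only the variable catalog inferred from
#'   the data when absent).
#' @export
read_cohort_csv <- function(dir) {
  obs <- read.csv(file.path(dir, "observations.csv"),
                  stringsAsFactors = FALSE)
  names(obs)[names(obs) == "t_days"] <- "t"
  static <- read.csv(file.path(dir, "static.csv"), stringsAsFactors = FALSE)
  structure(list(observations = obs, static = static,
                 ground_truth = NULL, config = NULL),
            class = "ckd_cohort")
}

#' Write the cohort assignment table
#'
#' @param assignments Output of [build_cohort()].
#' @param path CSV path.
#' @return The path, invisibly.
#' @export
write_assignments_csv <- function(assignments, path) {
  write.csv(assignments, path, row.names = FALSE)
  invisible(path)
}

#' Write an assembled (or matched) dataset to plain-text files
#'
#' Writes `meta.csv` (patient_id, label, seq_len, race, sex, age, T_last,
#' T_tra and, when present, match_id) and `sequences.csv`, a long-format
#' table of the per-patient feature matrices (patient_id, row, column,
#' value, observed) that round-trips exactly.
#'
#' @param dataset A `ckd_dataset`.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_dataset_csv <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(dataset$meta, file.path(dir, "meta.csv"), row.names = FALSE)
  rows <- lapply(dataset$meta$patient_id, function(id) {
    m <- dataset$series[[id]]$matrix
    k <- dataset$series[[id]]$mask
    data.frame(patient_id = id,
               row = rep(seq_len(nrow(m)), ncol(m)),
               column = rep(colnames(m), each = nrow(m)),
               value = as.vector(m), observed = as.vector(k),
               stringsAsFactors = FALSE)
  })
  write.csv(do.call(rbind, rows), file.path(dir, "sequences.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' Run the full pipeline from a cohort to a matched modeling dataset
#'
#' Convenience wrapper: [build_cohort()] then [assemble_dataset()] then
#' [match_controls()].
#'
#' @param cohort A `ckd_cohort`.
#' @param config An [assembly_config()].
#' @param spec A [match_spec()].
#' @param variables Optional variable subset applied before matching
#'   (e.g. `"egfr"` for the eGFR-only analysis); sequence lengths and
#'   matching keys are unaffected by the subset.
#' @return A matched `ckd_dataset`.
#' @export
build_matched_dataset <- function(cohort, config = assembly_config(),
                                  spec = match_spec(), variables = NULL) {
  assignments <- build_cohort(cohort)
  dataset <- assemble_dataset(cohort, assignments, config)
  if (!is.null(variables)) dataset <- subset_variables(dataset, variables)
  match_controls(dataset, spec)
}
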