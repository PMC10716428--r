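#' CKD stage bands on the eGFR scale
#'
#' Band definitions (mL/min/1.73m^2, all bounds inclusive) used for stable
#' period detection and cohort assignment: stage II \[60, 89\], stage III
#' \[30, 59\] with sub-stages IIIa \[45, 59\] and IIIb \[30, 44\], the
#' combined early band II_III \[30, 89\], and the late band IV_V (0, 29\].
#' A *stable period* in a band is a span of at least `min_span_days` days
#' during which every eGFR reading lies inside the band.
#'
#' @param min_span_days Minimum span of a stable period in days.
#' @return A list of bands (each `c(low, high)`) plus `min_span_days`.
#' @export
stage_bands <- function(min_span_days = 90) {
  stopifnot(min_span_days > 0)
  list(
    II = c(60, 89), III = c(30, 59), IIIa = c(45, 59), IIIb = c(30, 44),
    IV_V = c(0 + 1e-9, 29), II_III = c(30, 89),
    min_span_days = min_span_days
  )
}

#' Detect stable in-band episodes on an eGFR series
#'
#' A stable episode is a maximal run of consecutive readings all inside
#' `band` whose time span (last minus first reading of the run) is at least
#' `min_span` days. This is equivalent to the anchor-pair definition — two
#' in-band readings at least `min_span` days apart with every reading
#' between them also in band — after merging overlapping qualifying pairs
#' into maximal runs. Band bounds are inclusive.
#'
#' @param times Strictly increasing observation times in days.
#' @param values eGFR values (positive), same length as `times`.
#' @param band Numeric `c(low, high)`.
#' @param min_span Minimum span in days (default 90).
#' @return Data frame of disjoint, time-ordered episodes with columns
#'   `start_t`, `end_t`, `n_readings`; zero rows if none qualify.
#' @export
find_stable_episodes <- function(times, values, band, min_span = 90) {
  if (length(times) != length(values))
    stop("times and values must have equal length")
  if (length(times) == 0)
    return(data.frame(start_t = numeric(), end_t = numeric(),
                      n_readings = integer()))
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing")
  in_band <- values >= band[1] & values <= band[2]
  r <- rle(in_band)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  eps <- lapply(keep, function(k) {
    i <- starts[k]; j <- ends[k]
    if (times[j] - times[i] >= min_span)
      data.frame(start_t = times[i], end_t = times[j],
                 n_readings = j - i + 1L)
  })
  eps <- eps[!vapply(eps, is.null, logical(1))]
  if (length(eps) == 0)
    return(data.frame(start_t = numeric(), end_t = numeric(),
                      n_readings = integer()))
  do.call(rbind, eps)
}

#' Assign case/control/excluded status from an eGFR series
#'
#' Implements the cohort entry and outcome rules. A patient is *eligible*
#' only with at least four eGFR readings and at least one stable stage
#' II/III period (eGFR in \[30, 89\] for >= 90 days). An eligible patient
#' is a *case* if the series contains at least one stable stage IV/V period
#' (eGFR <= 29 for >= 90 days) and neither of the first two readings falls
#' inside such a period; the transition point `T_tra` is the time of the
#' first reading of the earliest stable stage IV/V period. An eligible
#' patient with no stable stage IV/V period is a *control*. Everyone else
#' is excluded with a reason code: `too_few_egfr`, `no_stable_early_period`,
#' or `first_readings_in_late_period`.
#'
#' @param times,values eGFR observation times (days) and values.
#' @param bands Band definitions from [stage_bands()].
#' @return A list with `status` (`"case"`, `"control"`, `"excluded"`),
#'   `T_tra` (days, `NA` unless case), `exclusion_reason` (`NA` unless
#'   excluded).
#' @export
assign_status <- function(times, values, bands = stage_bands()) {
  ms <- bands$min_span_days
  if (length(times) < 4)
    return(list(status = "excluded", T_tra = NA_real_,
                exclusion_reason = "too_few_egfr"))
  early <- find_stable_episodes(times, values, bands$II_III, ms)
  if (nrow(early) == 0)
    return(list(status = "excluded", T_tra = NA_real_,
                exclusion_reason = "no_stable_early_period"))
  late <- find_stable_episodes(times, values, bands$IV_V, ms)
  if (nrow(late) == 0)
    return(list(status = "control", T_tra = NA_real_,
                exclusion_reason = NA_character_))
  first_two <- times[1:2]
  in_late <- vapply(first_two, function(t0)
    any(t0 >= late$start_t & t0 <= late$end_t), logical(1))
  if (any(in_late))
    return(list(status = "excluded", T_tra = NA_real_,
                exclusion_reason = "first_readings_in_late_period"))
  list(status = "case", T_tra = late$start_t[1],
       exclusion_reason = NA_character_)
}

#' Build the case/control cohort table from an observation table
#'
#' Applies [assign_status()] to every patient's eGFR series.
#'
#' @param cohort A `ckd_cohort` (or any list with `observations` in the
#'   long format `(patient_id, variable, t, value)`).
#' @param bands Band definitions from [stage_bands()].
#' @return Data frame with one row per patient: `patient_id`, `status`,
#'   `T_tra`, `exclusion_reason`.
#' @export
build_cohort <- function(cohort, bands = stage_bands()) {
  obs <- cohort$observations
  egfr <- obs[obs$variable == "egfr", ]
  egfr <- egfr[order(egfr$patient_id, egfr$t), ]
  sl <- split(egfr, egfr$patient_id)
  rows <- lapply(names(sl), function(id) {
    d <- sl[[id]]
    a <- assign_status(d$t, d$value, bands)
    data.frame(patient_id = id, status = a$status, T_tra = a$T_tra,
               exclusion_reason = a$exclusion_reason,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
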