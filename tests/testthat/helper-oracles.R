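# Independent brute-force oracles for stable-episode detection and cohort
# assignment: test every index pair (i < j) for "both readings in band,
# span >= min_span, every reading between them in band", then merge
# overlapping qualifying pairs into maximal runs.

oracle_episodes <- function(times, values, band, min_span = 90) {
  empty <- data.frame(start_t = numeric(), end_t = numeric(),
                      n_readings = integer())
  n <- length(times)
  if (n == 0) return(empty)
  inb <- function(v) v >= band[1] & v <= band[2]
  pairs <- list()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j > i && inb(values[i]) && inb(values[j]) &&
        times[j] - times[i] >= min_span &&
        all(inb(values[i:j]))) {
      pairs[[length(pairs) + 1]] <- c(i, j)
    }
  }
  if (length(pairs) == 0) return(empty)
  m <- do.call(rbind, pairs)
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  merged <- list()
  cur <- m[1, ]
  for (r in seq_len(nrow(m))[-1]) {
    if (m[r, 1] <= cur[2]) cur[2] <- max(cur[2], m[r, 2])
    else { merged[[length(merged) + 1]] <- cur; cur <- m[r, ] }
  }
  merged[[length(merged) + 1]] <- cur
  do.call(rbind, lapply(merged, function(p)
    data.frame(start_t = times[p[1]], end_t = times[p[2]],
               n_readings = p[2] - p[1] + 1L)))
}

oracle_status <- function(times, values, bands = stage_bands()) {
  ms <- bands$min_span_days
  if (length(times) < 4)
    return(list(status = "excluded", T_tra = NA_real_,
                exclusion_reason = "too_few_egfr"))
  early <- oracle_episodes(times, values, bands$II_III, ms)
  if (nrow(early) == 0)
    return(list(status = "excluded", T_tra = NA_real_,
                exclusion_reason = "no_stable_early_period"))
  late <- oracle_episodes(times, values, bands$IV_V, ms)
  if (nrow(late) == 0)
    return(list(status = "control", T_tra = NA_real_,
                exclusion_reason = NA_character_))
  bad <- any(vapply(times[1:2], function(t0)
    any(t0 >= late$start_t & t0 <= late$end_t), logical(1)))
  if (bad)
    return(list(status = "excluded", T_tra = NA_real_,
                exclusion_reason = "first_readings_in_late_period"))
  list(status = "case", T_tra = late$start_t[1],
       exclusion_reason = NA_character_)
}

random_egfr_series <- function() {
  n <- sample(2:20, 1)
  times <- sort(runif(n, 0, 400))
  while (any(diff(times) <= 0)) times <- sort(runif(n, 0, 400))
  list(times = times, values = runif(n, 5, 95))
}
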