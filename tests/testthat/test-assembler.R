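toy_config <- assembly_config()

test_that("interval binning averages labs and takes the latest behavior code", {
  obs <- rbind(make_obs("A", "egfr", c(1, 3), c(10, 20)),
               make_obs("A", "smoking_status", c(1, 5), c(0, 1)))
  s <- bin_observations(obs, make_static("A"), toy_config)
  expect_equal(s$grid_times[1], 3.5)           # midpoint of [0, 7)
  expect_equal(unname(s$matrix[1, "egfr"]), 15)            # arithmetic mean
  expect_equal(unname(s$matrix[1, "smoking_status"]), 1)   # latest reading
  expect_equal(unname(s$matrix[, "time"]), s$grid_times)
  # demographics are constant observed columns
  expect_true(all(s$mask[, c("sex", "race_white")]))
  expect_error(bin_observations(make_obs("A", "serum_unobtainium", 1, 1),
                                make_static("A"), toy_config),
               "serum_unobtainium")
})

test_that("the time column is an arithmetic grid for generated patients", {
  coh <- small_cohort()
  obs_split <- split(coh$observations, coh$observations$patient_id)
  ids <- names(obs_split)[1:50]
  for (id in ids) {
    st <- coh$static[coh$static$patient_id == id, ]
    s <- bin_observations(obs_split[[id]], st, toy_config)
    expect_equal(diff(s$matrix[, "time"]),
                 rep(toy_config$t_w, nrow(s$matrix) - 1))
    expect_equal(s$matrix[, "time"], (seq_len(nrow(s$matrix)) - 0.5) * 7,
                 ignore_attr = TRUE)
    # binning is deterministic
    s2 <- bin_observations(obs_split[[id]], st, toy_config)
    expect_identical(s, s2)
  }
})

test_that("imputation fills forward, backward, then the training median", {
  m <- cbind(x = c(NA, 5, NA, NA), y = rep(NA_real_, 4))
  out <- impute_series(m, c(x = 0, y = 42))
  expect_equal(unname(out[, "x"]), c(5, 5, 5, 5))
  expect_equal(unname(out[, "y"]), rep(42, 4))
  # observed entries unchanged, no missingness left
  m2 <- cbind(x = c(1, NA, 3, NA), y = c(NA, 7, NA, 9))
  out2 <- impute_series(m2, c(x = 0, y = 0))
  expect_false(anyNA(out2))
  expect_equal(out2[c(1, 3), "x"], m2[c(1, 3), "x"])
  expect_equal(out2[c(2, 4), "y"], m2[c(2, 4), "y"])
  expect_equal(unname(out2[, "x"]), c(1, 1, 3, 3))
  expect_error(impute_series(m, c(x = 0)), "y")
})

test_that("the case window drops late points and checks validity", {
  obs <- make_obs("A", "egfr", seq(0, 400, by = 7), 55)
  s <- bin_observations(obs, make_static("A"), toy_config)
  w <- apply_case_window(s, T_tra = 200, toy_config)
  expect_true(w$valid)
  expect_true(all(w$series$grid_times < 193))
  # midpoints are 3.5 + 7k; the largest below 193 is 192.5, so the
  # transition sits 7.5 days past the last used point: inside the window
  expect_equal(max(w$series$grid_times), 192.5)
  expect_gte(200 - max(w$series$grid_times), toy_config$t_gap)
  expect_lte(200 - max(w$series$grid_times), toy_config$t_pre)
  # transition beyond the prediction window
  w2 <- apply_case_window(s, T_tra = 200,
                          assembly_config(t_pre = 365))
  expect_true(w2$valid)
  w3 <- apply_case_window(truncate_length(s, 100), T_tra = 600,
                          assembly_config(t_pre = 100))
  expect_false(w3$valid)
  expect_equal(w3$reason, "transition_outside_window")
  # too few remaining points
  w4 <- apply_case_window(s, T_tra = 30, toy_config)
  expect_false(w4$valid)
  expect_equal(w4$reason, "too_short")
})

test_that("control truncation removes the final prediction-window span", {
  obs <- make_obs("A", "egfr", seq(0, 730, by = 7), 55)
  s <- bin_observations(obs, make_static("A"), toy_config)
  expect_equal(max(s$grid_times), 731.5)
  w <- apply_control_truncation(s, toy_config)
  expect_true(w$valid)
  expect_true(all(w$series$grid_times <= 731.5 - 365))
  # series shorter than t_pre in span -> dropped
  short <- bin_observations(make_obs("A", "egfr", seq(0, 200, 10), 55),
                            make_static("A"), toy_config)
  w2 <- apply_control_truncation(short, toy_config)
  expect_false(w2$valid)
  # t_pre = 0 is rejected at config validation
  expect_error(assembly_config(t_pre = 0), "t_pre")
})

test_that("length truncation keeps the latest points only", {
  obs <- make_obs("A", "egfr", seq(0, 7 * 149, by = 7), 55)
  s <- bin_observations(obs, make_static("A"), toy_config)
  expect_equal(nrow(s$matrix), 150)
  tr <- truncate_length(s, 100)
  expect_equal(nrow(tr$matrix), 100)
  expect_equal(tr$grid_times, s$grid_times[51:150])
  expect_identical(truncate_length(tr, 100), tr)  # no-op below the cap
})

test_that("stage-IIIb exclusion truncates the stream at the first eGFR <= 44", {
  obs <- rbind(make_obs("A", "egfr", c(0, 100, 200, 300), c(80, 60, 43, 25)),
               make_obs("A", "sbp", c(50, 250), c(130, 135)))
  out <- exclude_stage_IIIb(obs)
  expect_true(all(out$t < 200))
  expect_false(any(out$variable == "sbp" & out$t == 250))
  # a patient never below 45 is untouched
  obs2 <- make_obs("B", "egfr", c(0, 100), c(80, 60))
  expect_identical(exclude_stage_IIIb(obs2), obs2)
})

test_that("assembled samples are labeled and leakage-free", {
  coh <- small_cohort()
  asn <- build_cohort(coh)
  ds <- assemble_dataset(coh, asn, toy_config)
  expect_true(all(ds$meta$label %in% 0:1))
  case_ids <- asn$patient_id[asn$status == "case"]
  expect_true(all(ds$meta$patient_id[ds$meta$label == 1] %in% case_ids))
  expect_true(all(ds$meta$seq_len <= toy_config$max_len))
  expect_true(all(ds$meta$seq_len >= toy_config$min_case_len))
  for (i in seq_len(nrow(ds$meta))) {
    s <- ds$series[[ds$meta$patient_id[i]]]
    expect_equal(unname(s$matrix[, "time"]), s$grid_times)
    if (ds$meta$label[i] == 1) {
      # no case feature vector at or past T_tra - t_gap
      expect_true(all(s$grid_times < ds$meta$T_tra[i] - toy_config$t_gap))
      gap <- ds$meta$T_tra[i] - ds$meta$T_last[i]
      expect_true(gap >= toy_config$t_gap && gap <= toy_config$t_pre)
    }
  }
})

test_that("excluding stage IIIb information reduces the number of valid cases", {
  coh <- memo("iiib_cohort",
              generate_cohort(generator_config(n_patients = 400, seed = 55)))
  asn <- build_cohort(coh)
  with_iiib <- assemble_dataset(coh, asn, assembly_config())
  without_iiib <- assemble_dataset(coh, asn,
                                   assembly_config(exclude_IIIb = TRUE))
  n_with <- sum(with_iiib$meta$label == 1)
  n_without <- sum(without_iiib$meta$label == 1)
  expect_lt(n_without, n_with)
  # the excluded-IIIb feature streams carry no eGFR reading <= 44
  for (id in without_iiib$meta$patient_id[without_iiib$meta$label == 1]) {
    m <- without_iiib$series[[id]]$matrix
    expect_true(all(is.na(m[, "egfr"]) | m[, "egfr"] > 44))
  }
})

test_that("variable subsetting keeps the time feature and the mapping", {
  ds <- small_matched()
  sub <- subset_variables(ds, "egfr")
  expect_equal(colnames(sub$series[[1]]$matrix), c("time", "egfr"))
  sub2 <- subset_variables(ds, c("egfr", "race"))
  expect_setequal(colnames(sub2$series[[1]]$matrix),
                  c("time", "egfr", "race_african_american", "race_white"))
  expect_error(subset_variables(ds, "not_a_variable"), "not_a_variable")
})
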