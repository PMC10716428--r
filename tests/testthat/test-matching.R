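# build a ckd_dataset skeleton with constructed matching keys; series are
# minimal one-column stubs (matching only reads the meta table)
keyed_dataset <- function(meta) {
  series <- lapply(seq_len(nrow(meta)), function(i) {
    n <- meta$seq_len[i]
    m <- cbind(time = (seq_len(n) - 0.5) * 7, egfr = 50)
    structure(list(grid_times = m[, "time"], matrix = m,
                   mask = !is.na(m), var_map = list(egfr = "egfr")),
              class = "ckd_series")
  })
  names(series) <- meta$patient_id
  structure(list(meta = meta, series = series,
                 config = assembly_config(), var_map = list(egfr = "egfr")),
            class = "ckd_dataset")
}

key_row <- function(id, label, seq_len = 10, race = "white", sex = "female",
                    age = 60) {
  data.frame(patient_id = id, label = label, seq_len = seq_len, race = race,
             sex = sex, age = age, T_last = seq_len * 7 - 3.5,
             T_tra = if (label == 1) seq_len * 7 + 100 else NA_real_,
             stringsAsFactors = FALSE)
}

test_that("a fully supplied case takes the four nearest-age controls", {
  meta <- rbind(key_row("case1", 1, age = 60),
                do.call(rbind, lapply(1:10, function(i)
                  key_row(sprintf("ctl%02d", i), 0, age = 60 + i / 4))))
  md <- match_controls(keyed_dataset(meta), match_spec(seed = 1))
  tab <- attr(md, "match_table")
  expect_equal(nrow(tab), 4)
  expect_setequal(tab$control_id, sprintf("ctl%02d", 1:4))
  expect_equal(sum(md$meta$label == 0), 4)
})

test_that("scarce controls yield a partial match that is recorded", {
  meta <- rbind(key_row("case1", 1),
                key_row("ctl1", 0), key_row("ctl2", 0),
                key_row("far", 0, age = 80))   # outside the age tolerance
  md <- match_controls(keyed_dataset(meta), match_spec(seed = 1))
  dg <- attr(md, "match_diagnostics")
  expect_equal(dg$achieved_ratio, 2)
  expect_setequal(attr(md, "match_table")$control_id, c("ctl1", "ctl2"))
})

test_that("exact keys are always respected", {
  meta <- rbind(key_row("case1", 1, race = "white", sex = "male", seq_len = 8),
                key_row("c1", 0, race = "white", sex = "male", seq_len = 8),
                key_row("c2", 0, race = "others", sex = "male", seq_len = 8),
                key_row("c3", 0, race = "white", sex = "female", seq_len = 8),
                key_row("c4", 0, race = "white", sex = "male", seq_len = 9))
  md <- match_controls(keyed_dataset(meta), match_spec(seed = 2))
  expect_equal(attr(md, "match_table")$control_id, "c1")
})

test_that("greedy matching attains the optimal total on constructed pools", {
  # three strata; capacities 4, 2, 0 -> optimum = sum over strata of
  # min(ratio * cases, controls) = 4 + 2 + 0
  meta <- rbind(
    key_row("caseA", 1, race = "white", seq_len = 10),
    do.call(rbind, lapply(1:6, function(i)
      key_row(paste0("wA", i), 0, race = "white", seq_len = 10))),
    key_row("caseB", 1, race = "others", seq_len = 12),
    key_row("oB1", 0, race = "others", seq_len = 12),
    key_row("oB2", 0, race = "others", seq_len = 12),
    key_row("caseC", 1, race = "African American", seq_len = 9))
  md <- match_controls(keyed_dataset(meta), match_spec(seed = 3))
  expect_equal(nrow(attr(md, "match_table")), 6)
  dg <- attr(md, "match_diagnostics")
  expect_equal(sort(dg$achieved_ratio), c(0, 2, 4))
  # shared stratum where controls exactly cover both cases
  meta2 <- rbind(
    key_row("case1", 1), key_row("case2", 1),
    do.call(rbind, lapply(1:8, function(i) key_row(paste0("s", i), 0))))
  md2 <- match_controls(keyed_dataset(meta2), match_spec(seed = 4))
  expect_equal(nrow(attr(md2, "match_table")), 8)
})

test_that("matched controls reproduce the case sequence-length marginal", {
  set.seed(9)
  lens <- sample(c(10, 20, 30), 12, replace = TRUE)
  cases <- do.call(rbind, lapply(seq_along(lens), function(i)
    key_row(sprintf("case%02d", i), 1, seq_len = lens[i])))
  controls <- do.call(rbind, lapply(1:200, function(i)
    key_row(sprintf("ctl%03d", i), 0,
            seq_len = sample(c(10, 20, 30), 1))))
  md <- match_controls(keyed_dataset(rbind(cases, controls)),
                       match_spec(seed = 10))
  dg <- attr(md, "match_diagnostics")
  expect_true(all(dg$achieved_ratio == 4))
  case_marginal <- table(md$meta$seq_len[md$meta$label == 1])
  ctl_marginal <- table(md$meta$seq_len[md$meta$label == 0])
  expect_equal(as.numeric(ctl_marginal), 4 * as.numeric(case_marginal))
})

test_that("matching is deterministic under a fixed seed", {
  ds <- small_matched()  # built from a fixed seed already
  coh <- small_cohort()
  a <- build_matched_dataset(coh, spec = match_spec(seed = 5))
  expect_identical(attr(a, "match_table"), attr(ds, "match_table"))
  expect_identical(a$meta, ds$meta)
})

test_that("permuting input rows does not change the matches", {
  set.seed(14)
  meta <- rbind(
    do.call(rbind, lapply(1:5, function(i)
      key_row(sprintf("case%d", i), 1, age = 55 + i))),
    do.call(rbind, lapply(1:30, function(i)
      key_row(sprintf("ctl%02d", i), 0, age = 52 + i / 3))))
  m1 <- match_controls(keyed_dataset(meta), match_spec(seed = 6))
  perm <- keyed_dataset(meta[sample(nrow(meta)), , drop = FALSE])
  m2 <- match_controls(perm, match_spec(seed = 6))
  norm <- function(m) {
    t <- attr(m, "match_table")
    t <- t[order(t$case_id, t$control_id), ]
    rownames(t) <- NULL
    t
  }
  expect_identical(norm(m1), norm(m2))
})

test_that("duplicate patient ids are rejected", {
  meta <- rbind(key_row("dup", 1), key_row("dup", 0))
  expect_error(match_controls(keyed_dataset(meta)), "duplicate")
})
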