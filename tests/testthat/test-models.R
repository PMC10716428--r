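# two-step toy sequences, linearly separable through the last eGFR value
separable_tensor <- function(n = 80, noise = 0.05, seed = 1) {
  set.seed(seed)
  y <- rep(0:1, length.out = n)
  X <- array(0, dim = c(4, 2, n))
  for (i in seq_len(n)) {
    lvl <- if (y[i] == 1) -1 else 1
    X[3:4, 1, i] <- rnorm(2, lvl, noise)
    X[3:4, 2, i] <- rnorm(2)
  }
  list(X = X, len = rep(2L, n), y = y)
}

test_that("case weight equals the control-to-case ratio of the training set", {
  w <- class_weights(c(rep(0, 100), rep(1, 25)))
  expect_equal(w$case_weight, 4.0)
  expect_equal(w$control_weight, 1)
  expect_error(class_weights(rep(0, 10)), "both classes")
})

test_that("LSTM softmax probabilities sum to one", {
  tr <- separable_tensor(40)
  cfg <- tiny_lstm_cfg(max_epochs = 3)
  cfg$max_len <- 4
  set.seed(2)
  fit <- fit_lstm(tr, tr, cfg)
  p <- predict(fit, tr)
  expect_true(all(abs(rowSums(p) - 1) < 1e-6))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("the LSTM separates a linearly separable toy within 200 epochs", {
  tr <- separable_tensor(80)
  cfg <- lstm_config("essential_variables", lstm_units = 8,
                     dense_layer_sizes = 8L, dropout_grid = 0,
                     max_epochs = 200, patience = 200, batch_size = 16,
                     learning_rate = 1e-2, max_len = 4)
  set.seed(3)
  fit <- fit_lstm(tr, tr, cfg)
  expect_equal(auroc(tr$y, score_risk(fit, tr)), 1.0)
})

test_that("LSTM training is reproducible under a fixed seed", {
  tr <- separable_tensor(40)
  cfg <- tiny_lstm_cfg(max_epochs = 4)
  cfg$max_len <- 4
  set.seed(11); f1 <- fit_lstm(tr, tr, cfg)
  set.seed(11); f2 <- fit_lstm(tr, tr, cfg)
  expect_identical(f1$weights, f2$weights)
  expect_identical(score_risk(f1, tr), score_risk(f2, tr))
})

test_that("single-class training sets and over-long sequences are rejected", {
  tr <- separable_tensor(20)
  tr$y <- rep(0L, 20)
  cfg <- tiny_lstm_cfg()
  expect_error(fit_lstm(tr, tr, cfg), "both classes")
  ds <- small_matched()
  stats <- preprocess_stats(ds)
  expect_error(dataset_tensor(ds, stats, max_len = 10), "longer than")
})

test_that("static Cox recovers a known log hazard ratio", {
  set.seed(21)
  n <- 2000
  x <- rbinom(n, 1, 0.5)
  df <- data.frame(time = rexp(n, rate = 0.02 * 2^x), event = 1, x = x)
  fit <- fit_cox_static(df, horizon = 30)
  est <- unname(coef(fit$fit)["x"])
  se <- sqrt(fit$fit$var[1, 1])
  expect_lt(abs(est - log(2)), 3 * se)
  # risk scores are monotone in the covariate and inside [0, 1]
  p <- predict(fit, data.frame(x = c(0, 1)))
  expect_true(all(p >= 0 & p <= 1))
  expect_gt(p[2], p[1])
})

test_that("an all-censored input raises an error", {
  df <- data.frame(time = rexp(20), event = 0, x = rnorm(20))
  expect_error(fit_cox_static(df), "events")
})

test_that("covariate column order does not change Cox predictions", {
  set.seed(22)
  n <- 300
  df <- data.frame(time = rexp(n), event = rbinom(n, 1, 0.6),
                   a = rnorm(n), b = rnorm(n))
  new <- data.frame(a = rnorm(5), b = rnorm(5))
  f1 <- fit_cox_static(df, horizon = 1)
  f2 <- fit_cox_static(df[, c("time", "event", "b", "a")], horizon = 1)
  expect_equal(predict(f1, new), predict(f2, new), tolerance = 1e-10)
})

test_that("constant covariate columns are dropped with a message", {
  df <- data.frame(time = rexp(50), event = rbinom(50, 1, 0.5),
                   x = rnorm(50), flat = 1)
  expect_message(fit <- fit_cox_static(df, horizon = 1), "flat")
  expect_false("flat" %in% fit$covars)
})

test_that("counting-process expansion is contiguous and lossless", {
  ds <- small_matched()
  stats <- preprocess_stats(ds)
  cp <- ckdprog:::dataset_cox_dynamic(ds, stats, t_pre = 365)
  for (id in ds$meta$patient_id[1:25]) {
    rows <- cp[cp$patient_id == id, ]
    i <- match(id, ds$meta$patient_id)
    expect_equal(nrow(rows), ds$meta$seq_len[i])
    expect_true(all(rows$stop > rows$start))
    expect_equal(rows$start[-1], rows$stop[-nrow(rows)])
    t_end <- if (ds$meta$label[i] == 1) ds$meta$T_tra[i]
             else ds$meta$T_last[i] + 365
    expect_equal(sum(rows$stop - rows$start), t_end - rows$start[1])
    expect_equal(sum(rows$event), ds$meta$label[i])
  }
})

test_that("dynamic Cox equals static Cox when covariates are constant", {
  set.seed(23)
  n <- 60
  x <- rnorm(n); z <- rbinom(n, 1, 0.5)
  tt <- rexp(n, 0.5 * exp(0.5 * x))
  ev <- rbinom(n, 1, 0.7)
  static_df <- data.frame(time = tt, event = ev, x = x, z = z)
  dyn <- do.call(rbind, lapply(seq_len(n), function(i) {
    cuts <- c(0, tt[i] / 3, 2 * tt[i] / 3, tt[i])
    data.frame(patient_id = sprintf("p%02d", i),
               start = cuts[1:3], stop = cuts[2:4],
               event = c(0, 0, ev[i]), x = x[i], z = z[i])
  }))
  fs <- fit_cox_static(static_df, horizon = 1)
  fd <- fit_cox_dynamic(dyn, horizon = 1)
  expect_equal(coef(fs$fit), coef(fd$fit), tolerance = 1e-6)
})

test_that("overlapping counting-process intervals are rejected", {
  bad <- data.frame(patient_id = "p", start = c(0, 5), stop = c(10, 15),
                    event = c(0, 1), x = c(1, 2))
  expect_error(fit_cox_dynamic(bad), "overlapping")
})

test_that("snapshot baselines behave at the no-signal and separable extremes", {
  # pure noise: mean test AUROC near 1/2
  for (kind in c("random_forest", "gbdt")) {
    aucs <- vapply(1:10, function(s) {
      set.seed(s)
      x <- matrix(rnorm(200 * 5), 200,
                  dimnames = list(NULL, paste0("v", 1:5)))
      y <- rbinom(200, 1, 0.5)
      fit <- fit_snapshot_baseline(list(x = x[1:100, ], y = y[1:100]),
                                   list(x = x[101:150, ], y = y[101:150]),
                                   kind, ntree = 100)
      auroc(y[151:200], score_risk(fit, x[151:200, ]))
    }, numeric(1))
    expect_gt(mean(aucs), 0.4)
    expect_lt(mean(aucs), 0.6)
  }
  # threshold-separable feature: perfect test AUROC
  set.seed(41)
  y <- rep(0:1, 60)
  x <- matrix(y * 2 - 1, 120, dimnames = list(NULL, "signal"))
  for (kind in c("random_forest", "gbdt")) {
    fit <- fit_snapshot_baseline(list(x = x[1:80, , drop = FALSE], y = y[1:80]),
                                 list(x = x[81:100, , drop = FALSE],
                                      y = y[81:100]), kind)
    expect_equal(auroc(y[101:120],
                       score_risk(fit, x[101:120, , drop = FALSE])), 1.0)
  }
  expect_error(fit_snapshot_baseline(list(x = x[1:10, , drop = FALSE],
                                          y = rep(1, 10)),
                                     NULL, "random_forest"), "both classes")
})
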