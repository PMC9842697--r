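test_that("window construction enumerates exhaustive stride-spaced windows", {
  x <- matrix(1:10, ncol = 1)
  ds <- make_windows(x, 1:10, in_len = 3, horizon = 2)
  expect_identical(nrow(ds$Y), 6L)
  expect_equal(ds$X[1, , 1], 1:3)
  expect_equal(ds$Y[1, ], 4:5)           # target starts one step after input
  expect_equal(ds$Y[6, ], 9:10)
  ## minimal and stride-limited cases give a single window
  expect_identical(nrow(make_windows(x, 1:10, 8, 2)$Y), 1L)
  expect_identical(nrow(make_windows(x, 1:10, 3, 2, stride = 10)$Y), 1L)
  expect_error(make_windows(x, 1:10, 9, 2), "shorter")
})

test_that("shuffling permutes reproducibly and preserves the window multiset", {
  set.seed(1)
  x <- matrix(stats::rnorm(60), ncol = 2)
  ds <- make_windows(x, stats::rnorm(30), 5, 2)
  s1 <- shuffle_windows(ds, seed = 4)
  s2 <- shuffle_windows(ds, seed = 4)
  expect_identical(s1$starts, s2$starts)
  expect_identical(s1$order, "shuffled")
  expect_setequal(s1$starts, ds$starts)
  expect_equal(s1$Y[order(s1$starts), ], ds$Y[order(ds$starts), ])
  ## single window: shuffling is the identity
  one <- make_windows(x, stats::rnorm(30), 28, 2)
  expect_identical(shuffle_windows(one, 9)$starts, one$starts)
})

test_that("a linear model forecasts a noise-free linear trend exactly", {
  y <- seq(0, 50, length.out = 200)
  ds <- make_windows(matrix(y, ncol = 1), y, in_len = 10, horizon = 5)
  res <- multivariate_forecast(ds, estimator_linear(), eval_split = 0.6)
  expect_lt(res$rmse, 1e-6)
})

test_that("shuffled-window training does not forecast worse than sliding order", {
  r <- simulate_culture(sim_config(seed = 13))
  cond <- condense_to_minutely(r$ranger)
  full <- merge_frames(r$scada, cond)
  keep <- c("cum_Air", "m_pH", "m_dO", "fr_Air", "fr_CO2")
  sub <- time_channel_frame(full$time, full$channels[keep], 60, "min")
  target <- tcf_channel(full, "PTI")
  idx <- seq(1, tcf_length(sub), by = 4)   # 4-minute grid for speed
  sub4 <- time_channel_frame(sub$time[idx], sub$channels[idx, ], 240, "min")
  ds <- make_windows(sub4, target[idx], in_len = 15, horizon = 5)
  sgd <- estimator_sgd_linear(lr = 0.05, epochs = 2)
  slide <- multivariate_forecast(ds, sgd, eval_split = 0.75)
  shuf <- multivariate_forecast(shuffle_windows(ds, seed = 2), sgd,
                                eval_split = 0.75)
  expect_lte(shuf$rmse, slide$rmse)
})

test_that("soft-sensor accuracy improves with the training fraction", {
  r <- simulate_culture(sim_config(seed = 17))
  cond <- condense_to_minutely(r$ranger)
  full <- merge_frames(r$scada, cond)
  keep <- c("cum_Air", "cum_CO2", "m_pH", "m_dO", "fr_Air")
  X <- as.matrix(full$channels[keep])
  y <- tcf_channel(full, "PTI")
  fits <- lapply(c(0.25, 0.5, 0.75), function(fr)
    soft_sensor_fit(X, y, train_fraction = fr))
  rmses <- vapply(fits, function(f) f$result$rmse, 0)
  expect_lte(rmses[3], rmses[2])
  expect_lte(rmses[2], rmses[1])
  expect_gt(fits[[3]]$result$r_squared, 0.9)
  ## feature-importance hook is exposed
  expect_true(is.null(fits[[3]]$importances) ||
                length(fits[[3]]$importances) >= 1)
  ## a feature-copy target is reproduced almost exactly
  copy <- soft_sensor_fit(X, X[, "cum_Air"], train_fraction = 0.75,
                          estimator_spec = estimator_linear())
  expect_lt(copy$result$rmse, 1e-3)
  ## permuted-target negative control carries no signal
  set.seed(5)
  perm <- soft_sensor_fit(X, sample(y), train_fraction = 0.75,
                          estimator_spec = estimator_linear())
  expect_lt(perm$result$r_squared, 0.1)
  expect_error(soft_sensor_fit(X, y, train_fraction = 1.2), "between")
})

test_that("univariate forecasting handles constant, smooth and step-change series", {
  expect_equal(univariate_forecast(rep(5, 120))$rmse, 0)
  ramp <- seq(0, 10, length.out = 120)
  expect_lt(univariate_forecast(ramp)$rmse, 0.01 * diff(range(ramp)))
  expect_error(univariate_forecast(1:50), "shorter")
})

test_that("expanding-window cross-validation never leaks future windows", {
  set.seed(2)
  x <- matrix(stats::rnorm(240), ncol = 2)
  ds <- make_windows(x, stats::rnorm(120), 10, 5)
  folds <- cross_validate_forecaster(ds, k = 4)
  expect_length(folds, 4L)
  for (f in folds) {
    tr <- attr(f, "train_idx"); va <- attr(f, "val_idx")
    expect_lt(max(ds$starts[tr]), min(ds$starts[va]))
    expect_gte(f$rmse, 0)
  }
  folds2 <- cross_validate_forecaster(ds, k = 4)
  expect_equal(vapply(folds, `[[`, 0, "rmse"),
               vapply(folds2, `[[`, 0, "rmse"))
  ## white-noise target: mean fold RMSE near the noise sd
  dsn <- make_windows(matrix(stats::rnorm(400), ncol = 1),
                      stats::rnorm(400), 5, 1)
  rms <- vapply(cross_validate_forecaster(dsn, 3), `[[`, 0, "rmse")
  expect_lt(abs(mean(rms) - 1), 0.3)
  expect_error(cross_validate_forecaster(ds, 1), "k must be")
})
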