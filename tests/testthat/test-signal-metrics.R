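dt5s <- 5 / 60

test_that("MRI filter is exact on polynomials up to the model order", {
  t <- (0:599) * dt5s
  ## constant: derivative identically zero
  expect_equal(compute_mri_vector(rep(3.7, 600), dt5s), rep(0, 600),
               tolerance = 1e-9)
  ## quadratic a + b t + c t^2 lies in the model class: MRI = b + 2 c t
  y <- 5 - 2 * t + 0.3 * t^2
  mri <- compute_mri_vector(y, dt5s, mri_params(61))
  expect_lt(max(abs(mri - (-2 + 0.6 * t))), 1e-9)
})

test_that("MRI filter matches the per-window least-squares oracle on random cubics", {
  set.seed(7)
  for (case in 1:5) {
    co <- stats::rnorm(4)
    t <- (0:299) * dt5s
    y <- co[1] + co[2] * t + co[3] * t^2 + co[4] * t^3 +
      stats::rnorm(300, sd = 0.1)
    p <- 21L; h <- 10L
    mri <- compute_mri_vector(y, dt5s, mri_params(p))
    for (j in c(1L, 4L, 11L, 150L, 290L, 300L)) {
      idx <- max(1L, j - h):min(300L, j + h)
      expect_equal(mri[j], oracle_window_slope(y, idx, j, dt5s),
                   tolerance = 1e-7, label = paste("case", case, "j", j))
    }
  }
})

test_that("MRI derivation is linear in its input", {
  set.seed(8)
  y1 <- cumsum(stats::rnorm(400)); y2 <- cumsum(stats::rnorm(400))
  m1 <- compute_mri_vector(y1, dt5s)
  m2 <- compute_mri_vector(y2, dt5s)
  m12 <- compute_mri_vector(2 * y1 - 3 * y2, dt5s)
  expect_equal(m12, 2 * m1 - 3 * m2, tolerance = 1e-9)
})

test_that("causal MRI windows agree with the trailing-window oracle", {
  set.seed(9)
  y <- cumsum(stats::rnorm(200))
  p <- 15L
  mri <- compute_mri_vector(y, dt5s, mri_params(p, centered = FALSE))
  for (j in c(40L, 120L, 200L)) {
    idx <- (j - p + 1L):j
    expect_equal(mri[j], oracle_window_slope(y, idx, j, dt5s),
                 tolerance = 1e-7)
  }
})

test_that("minutely condensation averages non-missing cells per minute", {
  x <- time_channel_frame((0:35) * 5, list(v = rep(5, 36)), 5, "s")
  expect_equal(condense_to_minutely(x)$channels$v, c(5, 5, 5))
  x2 <- time_channel_frame((0:11) * 5, list(v = 1:12), 5, "s")
  expect_equal(condense_to_minutely(x2)$channels$v, 6.5)
  v <- c(rep(NA, 6), 1:6)
  x3 <- time_channel_frame((0:11) * 5, list(v = v), 5, "s")
  expect_equal(condense_to_minutely(x3)$channels$v, mean(1:6))
  v4 <- c(rep(NA, 12), 1:12)
  x4 <- time_channel_frame((0:23) * 5, list(v = v4), 5, "s")
  expect_identical(condense_to_minutely(x4)$channels$v[1], NA_real_)
})

test_that("condensation of a noise-free simulated signal conserves minute means", {
  cfg <- sim_config(seed = 4, noise_sigma_pti = 0)
  r <- simulate_culture(cfg)
  cond <- condense_to_minutely(r$ranger)
  minute <- floor(r$truth$t_r_min)
  ref <- as.numeric(tapply(r$truth$pti_true, minute, mean))
  expect_equal(cond$channels$PTI, ref, tolerance = 1e-9)
})

test_that("PTI shift reproduces the printed comparison and its invariances", {
  t_h <- seq(0, 68, by = 1 / 60)
  mk <- function(end_val) {
    y <- stats::approx(c(0, 46, 68), c(20, 100, end_val), xout = t_h)$y
    structure(y, time_h = t_h)
  }
  low <- mk(455)    # PTI rising by +355 RU after divergence at 46 h
  unopt <- mk(295)  # +195 RU
  s_low <- pti_shift(low, 46, 68)
  s_unopt <- pti_shift(unopt, 46, 68)
  expect_equal(s_low, 355, tolerance = 1e-6)
  expect_equal(s_unopt, 195, tolerance = 1e-6)
  expect_equal(round(s_low / s_unopt, 1), 1.8)
  ## invariant to adding a constant
  expect_equal(pti_shift(structure(low + 1000, time_h = t_h), 46, 68),
               s_low, tolerance = 1e-9)
  ## constant series has zero shift; out-of-range times error
  expect_equal(pti_shift(structure(rep(2, length(t_h)), time_h = t_h),
                         10, 60), 0)
  expect_error(pti_shift(low, 46, 100), "outside")
  ## frames work too
  r <- simulate_culture(sim_config(seed = 1))
  expect_type(pti_shift(r$ranger, 46, 67), "double")
})

test_that("specific growth rate matches its closed form and regression variant", {
  mu <- 0.040
  t2 <- log(2) / mu
  expect_equal(specific_growth_rate(c(1e6, 2e6), c(0, t2)), 0.040,
               tolerance = 1e-12)
  expect_equal(specific_growth_rate(c(5e5, 5e5), c(0, 10)), 0)
  ## multi-point: least-squares slope of log VCC
  t <- c(0, 20, 45)
  vcc <- c(1e6, 2.3e6, 5.2e6)
  ref <- unname(stats::coef(stats::lm(log(vcc) ~ t))[2])
  expect_equal(specific_growth_rate(vcc, t), ref, tolerance = 1e-12)
  expect_error(specific_growth_rate(c(-1, 2), c(0, 1)), "positive")
})

test_that("assay conversions implement the titre and particle formulas", {
  expect_equal(functional_titre(10, 1e6, 10, 1), 1e6)
  expect_equal(functional_titre(0, 1e6, 10, 1), 0)
  expect_equal(functional_titre(5, 5e5, 100, 0.5), 5e6)
  expect_error(functional_titre(10, 1e6, 10, 0), "volume")
  expect_equal(total_particles(0), 0)
  expect_equal(total_particles(1e-9), 1e-9 / 2.4e4 * 6.022e23 / 2000,
               tolerance = 1e-12)
  expect_equal(total_particles(1e-9), 1.255e7, tolerance = 1e-3)
  ## linearity
  expect_equal(total_particles(3e-9), 3 * total_particles(1e-9))
})
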