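test_that("activity response is unimodal with its maximum at the configured optimum", {
  cfg <- sim_config()
  grid <- seq(6.0, 7.4, by = 0.1)
  act <- activity_response(grid, cfg)
  expect_equal(grid[which.max(act)], 6.4)
  ## strictly decreasing right of the optimum
  right <- act[grid >= 6.4]
  expect_true(all(diff(right) < 0))
  expect_lt(activity_response(7.00, cfg), activity_response(6.60, cfg))
  expect_equal(activity_response(cfg$ph_peak, cfg),
               max(activity_response(seq(5.5, 8, by = 0.005), cfg)))
  expect_error(activity_response(4.0, cfg), "physical range")
})

test_that("pH actuation follows a first-order lag with a hard floor", {
  cfg <- sim_config(actuator_tau_min = 30)
  ## closed-form response: step 7.0 -> 6.6 over one time constant
  expect_equal(actuate_ph(7.0, 6.6, dt = 30, cfg),
               7.0 - 0.4 * (1 - exp(-1)), tolerance = 1e-12)
  ## fixed point
  expect_equal(actuate_ph(6.8, 6.8, dt = 10, cfg), 6.8)
  ## setpoints below the floor saturate at the floor
  expect_equal(actuate_ph(7.0, 6.20, dt = 1e6, cfg), 6.40,
               tolerance = 1e-9)
})

test_that("simulation is deterministic and its ground truth is recoverable", {
  cfg <- sim_config(seed = 9)
  a <- simulate_culture(cfg)
  b <- simulate_culture(cfg)
  expect_identical(a$ranger$channels$PTI, b$ranger$channels$PTI)
  expect_identical(a$scada$channels$m_pH, b$scada$channels$m_pH)
  expect_identical(a$offline, b$offline)
  ## noise-free run: PTI is exactly the activity integral, and MRI
  ## recovers the activity response of the achieved pH
  cfg0 <- sim_config(seed = 9, noise_sigma_pti = 0)
  r0 <- simulate_culture(cfg0)
  expect_equal(r0$ranger$channels$PTI, r0$truth$pti_true)
  interior <- seq(5000, 15000)   # inside phase 1, away from edges/steps
  expect_lt(max(abs(r0$ranger$channels$MRI[interior] -
                      r0$truth$activity[interior])), 1e-5)
})

test_that("a constant-activity noise-free plant integrates PTI linearly", {
  cfg <- sim_config(seed = 1, noise_sigma_pti = 0, act_amp = 0,
                    act_base = 2)
  ## flat activity of 2 RU/min; kill the phase structure via inductions
  ## beyond the horizon
  cfg$induction1_h <- 1e5; cfg$induction2_h <- 2e5
  r <- simulate_culture(cfg)
  t_min <- r$truth$t_r_min
  ## phase multiplier is 0.6 before induction 1
  expect_equal(r$ranger$channels$PTI, 2 * 0.6 * t_min, tolerance = 1e-9)
})

test_that("three activity phases appear and PTI rises monotonically on the dead-band run", {
  r <- simulate_culture(sim_config(seed = 5, noise_sigma_pti = 0))
  pti <- r$ranger$channels$PTI
  expect_true(all(diff(pti) >= -1e-12))
  t_h <- r$truth$t_r_min / 60
  slope <- function(lo, hi) {
    i <- t_h > lo & t_h < hi
    stats::coef(stats::lm(pti[i] ~ t_h[i]))[2]
  }
  s1 <- slope(2, 22); s2 <- slope(26, 42); s3 <- slope(46, 66)
  expect_gt(s2, s1)
  expect_gt(s3, s2)
})

test_that("low-pH operation roughly doubles cumulative air and slows growth", {
  sched <- probe_schedule(c(26, 36, 46), c(6.8, 6.6, 6.4))
  lo <- simulate_culture(sim_config(seed = 7, ph_deadband = 0.02), sched)
  hi <- simulate_culture(sim_config(seed = 7, ph_deadband = 0.02))
  ratio <- utils::tail(lo$scada$channels$cum_Air, 1) /
    utils::tail(hi$scada$channels$cum_Air, 1)
  expect_gte(ratio, 1.5)
  ## growth-rate ordering mu(6.40) < mu(7.00)
  cfg <- sim_config()
  expect_lt(patflux:::.mu_of_ph(6.40, cfg), patflux:::.mu_of_ph(7.00, cfg))
  expect_equal(patflux:::.mu_of_ph(7.00, cfg), 0.040)
  expect_equal(patflux:::.mu_of_ph(6.40, cfg), 0.031)
})

test_that("missingness injection blanks exactly the blackout cells of MRI only", {
  r <- simulate_culture(sim_config(seed = 2))
  out <- inject_missingness(r$ranger, setpoint_events = 30,
                            blackout_min = 10)
  ## 10 min at 5 s resolution = 120 cells
  expect_identical(sum(is.na(out$channels$MRI)), 120L)
  expect_identical(out$channels$PTI, r$ranger$channels$PTI)
  ## no events: a no-op
  same <- inject_missingness(r$ranger, numeric(0), 10)
  expect_identical(same$channels$MRI, r$ranger$channels$MRI)
  ## many events approach the extreme observed missingness
  events <- seq(1, 67, by = 0.5)
  heavy <- inject_missingness(r$ranger, events, blackout_min = 20)
  expect_gt(attr(heavy, "missing_fraction"), 0.5)
})

test_that("frame CSV round-trips preserve values and missing cells", {
  r <- simulate_culture(sim_config(seed = 3))
  masked <- inject_missingness(r$ranger, 30, 10)
  path <- withr::local_tempfile(fileext = ".csv")
  write_frame_csv(masked, path)
  back <- read_frame_csv(path)
  expect_equal(back$channels$PTI, masked$channels$PTI, tolerance = 1e-9)
  expect_identical(is.na(back$channels$MRI), is.na(masked$channels$MRI))
  expect_identical(back$time_unit, "s")
})
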