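test_that("mirrored schedules reflect about the centre and are involutive", {
  base <- probe_schedule(c(26, 30, 34, 38), c(6.7, 6.5, 6.7, 6.5),
                         centre = 6.6)
  pair <- make_mirrored_schedules(base)
  expect_equal(pair$mirror$setpoint, c(6.5, 6.7, 6.5, 6.7))
  expect_equal(pair$mirror$time_h, base$time_h)
  back <- make_mirrored_schedules(pair$mirror)$mirror
  expect_equal(back$setpoint, base$setpoint)
  ## flat schedule mirrors to itself
  flat <- probe_schedule(c(26, 40), c(6.6, 6.6))
  expect_equal(make_mirrored_schedules(flat)$mirror$setpoint,
               flat$setpoint)
  expect_error(probe_schedule(c(30, 26), c(6.6, 6.4)), "increase")
  expect_error(probe_schedule(26, 9), "5.5")
})

test_that("the autonomous decision rule probes down first, then follows MRI feedback", {
  empty <- structure(data.frame(time_h = numeric(0), setpoint = numeric(0),
                                achieved_ph = numeric(0),
                                mri_mean = numeric(0),
                                direction = numeric(0)),
                     class = c("probe_log", "data.frame"))
  first <- autonomous_next_setpoint(empty, c(1, 1, 1), current_ph = 6.60,
                                    step = 0.10)
  expect_equal(first$setpoint, 6.50)
  expect_identical(first$direction, -1)
  hist <- rbind(empty, data.frame(time_h = 26, setpoint = 6.5,
                                  achieved_ph = 6.6, mri_mean = 1.0,
                                  direction = -1))
  class(hist) <- c("probe_log", "data.frame")
  ## improvement after a downward step: continue downward
  dn <- autonomous_next_setpoint(hist, rep(1.2, 10), 6.50, 0.10)
  expect_identical(dn$direction, -1)
  expect_equal(dn$setpoint, 6.40)
  ## deterioration: reverse upward
  up <- autonomous_next_setpoint(hist, rep(0.8, 10), 6.50, 0.10)
  expect_identical(up$direction, 1)
  expect_equal(up$setpoint, 6.60)
  ## all-missing MRI window: decision deferred, setpoint held
  hold <- autonomous_next_setpoint(hist, rep(NA_real_, 10), 6.50, 0.10)
  expect_identical(hold$direction, 0)
  expect_equal(hold$setpoint, 6.5)
  ## bounds clamp
  clamped <- autonomous_next_setpoint(empty, 1, 5.85, 0.10,
                                      bounds = c(5.8, 7.4))
  expect_gte(clamped$setpoint, 5.8)
  expect_error(autonomous_next_setpoint(empty, 1, 6.6, -0.1), "positive")
})

test_that("pre-programmed probing shows higher MRI in low-pH segments", {
  sched <- probe_schedule(c(26, 32, 38, 44, 50, 56),
                          c(6.4, 6.8, 6.4, 6.8, 6.4, 6.8), centre = 6.6)
  cfg <- sim_config(seed = 15, ph_deadband = 0.02)
  res <- run_preprogrammed(sched, cfg)
  log <- res$log
  low <- log$mri_mean[log$setpoint == 6.4]
  high <- log$mri_mean[log$setpoint == 6.8]
  expect_gt(mean(low), mean(high))
  ## the mirror preserves the qualitative pH -> MRI ordering
  mir <- make_mirrored_schedules(sched)$mirror
  res_m <- run_preprogrammed(mir, cfg)
  low_m <- res_m$log$mri_mean[abs(res_m$log$setpoint - 6.4) < 1e-9]
  high_m <- res_m$log$mri_mean[abs(res_m$log$setpoint - 6.8) < 1e-9]
  expect_gt(mean(low_m), mean(high_m))
  ## an empty schedule reduces to a constant-setpoint run
  none <- run_preprogrammed(probe_schedule(numeric(0), numeric(0)), cfg)
  expect_identical(nrow(none$log), 0L)
  expect_error(run_preprogrammed(probe_schedule(80, 6.6), cfg), "duration")
})

test_that("autonomous probing is deterministic and respects floor and bounds", {
  cfg <- sim_config(seed = 23, ph_deadband = 0.02)
  a <- run_autonomous(cfg)
  b <- run_autonomous(cfg)
  expect_identical(a, b)
  expect_true(all(a$setpoint >= 5.8 & a$setpoint <= 7.4))
  expect_true(all(a$achieved_ph >= cfg$actuator_floor - 1e-9))
  expect_identical(a$direction[1], -1)   # first adjustment always down
  ## dwell spacing between decisions
  expect_true(all(abs(diff(a$time_h) - 1.5) < 1e-9))
})

test_that("autonomous probing recovers the plant optimum within one step", {
  log64 <- run_autonomous(sim_config(seed = 31, ph_deadband = 0.02,
                                     noise_sigma_pti = 0), step = 0.10)
  expect_lte(abs(attr(log64, "terminal_achieved_ph") - 6.40), 0.10 + 1e-6)
  log65 <- run_autonomous(sim_config(seed = 31, ph_deadband = 0.02,
                                     ph_peak = 6.50,
                                     noise_sigma_pti = 0), step = 0.05)
  expect_lte(abs(attr(log65, "terminal_achieved_ph") - 6.50), 0.05 + 1e-6)
  ## the large step homes in at least as fast as the small step
  n10 <- probe_decisions_to_reach(
    run_autonomous(sim_config(seed = 31, ph_deadband = 0.02), step = 0.10),
    6.40, tol = 0.05)
  n05 <- probe_decisions_to_reach(
    run_autonomous(sim_config(seed = 31, ph_deadband = 0.02), step = 0.05),
    6.40, tol = 0.05)
  expect_lte(n10, n05)
})
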