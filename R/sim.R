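#' Simulation configuration for the synthetic bioprocess plant
#'
#' Defaults encode the study conditions the generator emulates: a
#' 66-69 h production process sampled at 1/min (SCADA) and 1/5 s
#' (refractive-index probe), two induction events (the second ~20 h
#' after the first, accompanied by a volumetric bolus that steps the
#' PTI), a metabolic-activity optimum at pH 6.40, a first-order pH
#' actuator with a hard floor at pH 6.40 (CO2-sparging acidification
#' cannot drive the culture lower), and pH-dependent growth
#' interpolating specific growth rates of 0.040 1/h (pH 7.0) down to
#' 0.031 1/h (pH 6.4).
#'
#' @param duration_h process duration, hours (study range 66.15-69.25).
#' @param scada_period_s,ranger_period_s sampling periods, seconds; the
#'   probe period must divide the SCADA period.
#' @param induction1_h,induction2_h induction event times, hours.
#' @param ph_peak pH of maximal metabolic activity.
#' @param ph_init pH immediately post inoculation.
#' @param ph_setpoint default setpoint when no schedule is supplied.
#' @param ph_deadband controller dead-band half-width, pH units.
#' @param actuator_floor hard lower limit on achievable pH.
#' @param actuator_tau_min first-order actuator time constant, minutes.
#' @param noise_sigma_pti additive Gaussian noise on PTI, RU.
#' @param act_base,act_amp,act_slope,act_width activity response shape:
#'   Gaussian bump of amplitude `act_amp` (RU/min) and width `act_width`
#'   (pH units) centred at `ph_peak`, over a baseline
#'   `act_base + act_slope * (ph_init - ph)`. The default slope of 0
#'   keeps the maximum exactly at `ph_peak`.
#' @param mu_high,mu_low specific growth rates (1/h) at pH 7.0 and at
#'   pH `ph_peak`.
#' @param drift_per_min passive acidification drift inside the
#'   dead-band, pH/min.
#' @param vcc0 inoculation viable cell concentration, cells/mL.
#' @param seed RNG seed; every stochastic element derives from it.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(duration_h = 68, scada_period_s = 60,
                       ranger_period_s = 5,
                       induction1_h = 24, induction2_h = 44,
                       ph_peak = 6.40, ph_init = 7.20,
                       ph_setpoint = 7.00, ph_deadband = 0.20,
                       actuator_floor = 6.40, actuator_tau_min = 15,
                       noise_sigma_pti = 2,
                       act_base = 1.0, act_amp = 2.0, act_slope = 0,
                       act_width = 0.25,
                       mu_high = 0.040, mu_low = 0.031,
                       drift_per_min = 1e-4, vcc0 = 1e6, seed = 1L) {
  if (duration_h < 66.15 - 1e-9 || duration_h > 69.25 + 1e-9)
    warning("duration outside the emulated 66.15-69.25 h study range")
  if (scada_period_s %% ranger_period_s != 0)
    stop("ranger period must divide the SCADA period")
  if (actuator_floor > ph_peak + 0.2)
    stop("actuator floor incompatible with the activity optimum")
  structure(list(duration_h = duration_h, scada_period_s = scada_period_s,
                 ranger_period_s = ranger_period_s,
                 induction1_h = induction1_h, induction2_h = induction2_h,
                 ph_peak = ph_peak, ph_init = ph_init,
                 ph_setpoint = ph_setpoint, ph_deadband = ph_deadband,
                 actuator_floor = actuator_floor,
                 actuator_tau_min = actuator_tau_min,
                 noise_sigma_pti = noise_sigma_pti,
                 act_base = act_base, act_amp = act_amp,
                 act_slope = act_slope, act_width = act_width,
                 mu_high = mu_high, mu_low = mu_low,
                 drift_per_min = drift_per_min, vcc0 = vcc0,
                 seed = as.integer(seed)),
            class = "sim_config")
}

## evaluate `expr` under a local RNG stream; global .Random.seed untouched
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Ground-truth metabolic activity as a function of pH
#'
#' Unimodal response with its maximum at `config$ph_peak`; strictly
#' decreasing above the optimum. Encodes (qualitatively) that lower
#' culture pH yields higher metabolic-rate-index activity down to the
#' optimum.
#'
#' @param ph pH value(s), within the physical range 5.5-8.0.
#' @param config a [sim_config()].
#' @return activity in RU/min.
#' @export
activity_response <- function(ph, config = sim_config()) {
  if (any(ph < 5.5 - 1e-12) || any(ph > 8.0 + 1e-12))
    stop("pH outside physical range [5.5, 8.0]")
  config$act_base + config$act_slope * (config$ph_init - ph) +
    config$act_amp * exp(-((ph - config$ph_peak)^2) /
                           (2 * config$act_width^2))
}

#' One actuator step of the pH control loop
#'
#' First-order approach of the culture pH toward
#' `max(setpoint, actuator_floor)` with time constant
#' `actuator_tau_min`; the achieved pH never falls below the floor
#' (CO2-sparging acidification limit).
#'
#' @param current_ph achieved pH now.
#' @param setpoint commanded setpoint.
#' @param dt elapsed time, minutes (> 0).
#' @param config a [sim_config()].
#' @param tau_min optional override of the time constant (the plant uses
#'   this to emulate occasional PID sluggishness).
#' @return achieved pH after `dt`.
#' @export
actuate_ph <- function(current_ph, setpoint, dt, config = sim_config(),
                       tau_min = config$actuator_tau_min) {
  if (dt <= 0) stop("dt must be positive")
  target <- max(setpoint, config$actuator_floor)
  ph <- target + (current_ph - target) * exp(-dt / tau_min)
  max(ph, config$actuator_floor)
}

## Per-minute achieved-pH trajectory for a piecewise-constant setpoint
## schedule. Inside the dead-band the controller holds and the culture
## drifts acid-ward; outside it, a first-order approach to the clamped
## setpoint. Each schedule segment draws (seeded) whether the PID loop
## is distorted, doubling the time constant.
.ph_trajectory <- function(config, sch_times_h, sch_setpoints, n_min,
                           ph0 = config$ph_init) {
  sp <- rep(config$ph_setpoint, n_min)
  seg <- rep(0L, n_min)
  tmin <- seq_len(n_min) - 1
  for (k in seq_along(sch_times_h)) {
    idx <- tmin >= sch_times_h[k] * 60
    sp[idx] <- sch_setpoints[k]
    seg[idx] <- k
  }
  n_seg <- length(sch_times_h) + 1L
  distorted <- stats::runif(n_seg) < 0.2
  ph <- numeric(n_min)
  cur <- ph0
  for (i in seq_len(n_min)) {
    tau <- config$actuator_tau_min * if (distorted[seg[i] + 1L]) 2 else 1
    if (abs(cur - sp[i]) > config$ph_deadband) {
      cur <- actuate_ph(cur, sp[i], dt = 1, config = config, tau_min = tau)
    } else {
      cur <- max(cur - config$drift_per_min, config$actuator_floor)
    }
    ph[i] <- cur
  }
  list(ph = ph, sp = sp)
}

## pH-dependent specific growth rate, 1/h: linear between the printed
## endpoints (mu_low at ph_peak, mu_high at 7.0), clamped outside.
.mu_of_ph <- function(ph, config) {
  lo <- config$ph_peak; hi <- 7.0
  f <- pmin(pmax((ph - lo) / (hi - lo), 0), 1)
  config$mu_low + f * (config$mu_high - config$mu_low)
}

## phase multiplier: three activity phases separated by the inductions
.phase_mult <- function(t_h, config) {
  ifelse(t_h < config$induction1_h, 0.6,
         ifelse(t_h < config$induction2_h, 1.0, 1.4))
}

#' Simulate a full bioprocess run
#'
#' Generates SCADA (1/min, 18 channels), refractive-index probe
#' (EPT/PTI/MRI at the probe period) and offline sample streams with a
#' known ground truth. PTI is the cumulative integral of the activity
#' response at the achieved pH (scaled by the induction-phase
#' multiplier), plus a step discontinuity at the second induction
#' (volumetric bolus) and additive Gaussian noise; MRI derives from the
#' noisy PTI through the same local-quadratic filter the analysis
#' stages use. Cumulative air inflow grows faster below pH ~6.7
#' (CO2-stripping surrogate), and growth slows at low pH.
#'
#' @param config a [sim_config()].
#' @param schedule optional data.frame with columns `time_h`,
#'   `setpoint`: pH setpoint changes at the given process times.
#' @param offline_times_h sample times for the offline table (default: 5
#'   evenly spaced times; supply 7 for validation-style runs).
#' @return list with elements `scada`, `ranger` (both [time_channel_frame()]),
#'   `offline` (data.frame) and `truth` (noise-free PTI, achieved pH,
#'   growth-rate profile, configuration echo).
#' @export
simulate_culture <- function(config = sim_config(), schedule = NULL,
                             offline_times_h = NULL) {
  if (is.null(schedule))
    schedule <- data.frame(time_h = numeric(0), setpoint = numeric(0))
  if (nrow(schedule) &&
      (any(schedule$time_h < 0) || any(schedule$time_h > config$duration_h)))
    stop("schedule times outside the run duration")
  with_seed(config$seed, {
    n_min <- floor(config$duration_h * 60) + 1L
    t_min <- seq_len(n_min) - 1
    t_h <- t_min / 60
    traj <- .ph_trajectory(config, schedule$time_h, schedule$setpoint, n_min)
    ph_min <- traj$ph

    ## --- probe frame at ranger resolution -------------------------------
    dt_r_min <- config$ranger_period_s / 60
    t_r_min <- seq(0, (n_min - 1), by = dt_r_min)
    ph_r <- stats::approx(t_min, ph_min, xout = t_r_min)$y
    mult_r <- .phase_mult(t_r_min / 60, config)
    act_r <- activity_response(ph_r, config) * mult_r
    pti_true <- cumsum(act_r * dt_r_min) - act_r[1] * dt_r_min
    pti_true <- pti_true + 40 * (t_r_min / 60 >= config$induction2_h)
    pti <- pti_true + stats::rnorm(length(pti_true),
                                   sd = config$noise_sigma_pti)
    mri <- compute_mri_vector(pti, dt_min = dt_r_min,
                              params = mri_params())
    ranger <- time_channel_frame(
      t_r_min * 60, list(EPT = t_r_min * 60, PTI = pti, MRI = mri),
      period_s = config$ranger_period_s, time_unit = "s")

    ## --- SCADA frame at 1/min -------------------------------------------
    low_ph_boost <- stats::plogis((6.7 - ph_min) / 0.05)
    fr_air <- 0.05 * (1 + 2.0 * low_ph_boost) +
      stats::rnorm(n_min, sd = 1e-3)
    pushing_up <- ph_min < traj$sp - config$ph_deadband
    pushing_down <- ph_min > traj$sp + config$ph_deadband
    fr_co2 <- 0.005 + 0.03 * pushing_down + stats::rnorm(n_min, sd = 2e-4)
    fr_o2 <- 0.01 + 0.005 * low_ph_boost + stats::rnorm(n_min, sd = 2e-4)
    fr_n2 <- 0.002 + stats::rnorm(n_min, sd = 1e-4)
    alkali_rate <- 0.02 * pushing_up
    m_do <- 40 - 8 * low_ph_boost + stats::rnorm(n_min, sd = 0.3)
    scada <- time_channel_frame(t_min, list(
      EPT = t_min,
      cum_Alkali = cumsum(alkali_rate),
      cum_Air = cumsum(fr_air),
      cum_CO2 = cumsum(fr_co2),
      cum_N2 = cumsum(fr_n2),
      cum_O2 = cumsum(fr_o2),
      m_dO = m_do,
      m_pH = ph_min + stats::rnorm(n_min, sd = 0.002),
      m_Stirrer = rep(250, n_min),
      m_Temperature = rep(37, n_min),
      fr_Air = fr_air,
      fr_CO2 = fr_co2,
      fr_N2 = fr_n2,
      fr_O2 = fr_o2,
      sp_dO = rep(40, n_min),
      sp_pH = traj$sp,
      sp_Stirrer = rep(250, n_min),
      sp_Temperature = rep(37, n_min)),
      period_s = config$scada_period_s, time_unit = "min")

    ## --- offline samples -------------------------------------------------
    mu_min <- .mu_of_ph(ph_min, config)
    log_vcc <- log(config$vcc0) + cumsum(mu_min) / 60
    if (is.null(offline_times_h))
      offline_times_h <- seq(0, config$duration_h, length.out = 5)
    oi <- pmax(1L, pmin(n_min, round(offline_times_h * 60) + 1L))
    low_exposure_h <- cumsum(ph_min < 6.6) / 60
    frac_low <- low_exposure_h[n_min] / config$duration_h
    titre_end <- exp((1 - frac_low) * log(5.95e6) + frac_low * log(2.83e4))
    particles_end <- exp((1 - frac_low) * log(3.23e9) + frac_low * log(2.09e8))
    p24_end <- particles_end * 2000 * 2.4e4 / 6.022e23
    tt <- offline_times_h / config$duration_h
    offline <- data.frame(
      time_h = offline_times_h,
      vcc = exp(log_vcc[oi]),
      viability = pmax(70, 97 - 1.3 * tt * config$duration_h / 68 -
                         6 * low_exposure_h[oi] / config$duration_h * 10),
      aggregation = 1.5 + 1.5 * tt,
      titre_tu_ml = c(rep(NA_real_, length(oi) - 1), titre_end),
      p24_g_ml = c(rep(NA_real_, length(oi) - 1), p24_end),
      glucose = 30 - 18 * tt^1.2,
      lactate = 2 + 16 * tt,
      nh4 = 1 + 2 * tt,
      na = 140 - 2 * tt,
      k = 5 + 0.5 * tt,
      gln = 4 - 3 * tt,
      glu = 0.5 + 0.3 * tt)

    truth <- list(pti_true = pti_true, t_r_min = t_r_min,
                  ph_achieved = ph_min, setpoint = traj$sp, t_min = t_min,
                  mu = mu_min, activity = act_r,
                  phase_mult = mult_r, config = config)
    list(scada = scada, ranger = ranger, offline = offline, truth = truth)
  })
}

#' Blank out probe MRI data after setpoint events
#'
#' The probe does not record MRI immediately after a parameter change;
#' this masks the MRI channel for `blackout_min` minutes after each
#' event (PTI is untouched - that channel has virtually no gaps) and
#' reports the resulting missing fraction.
#'
#' @param ranger probe `tcf` with an `MRI` channel.
#' @param setpoint_events event times, hours.
#' @param blackout_min blackout duration per event, minutes.
#' @return the masked frame, with attribute `missing_fraction`.
#' @export
inject_missingness <- function(ranger, setpoint_events, blackout_min = 10) {
  if (blackout_min < 0) stop("blackout must be non-negative")
  t_min <- ranger$time / if (ranger$time_unit == "s") 60 else 1
  mri <- ranger$channels$MRI
  for (ev in setpoint_events) {
    ev_min <- ev * 60
    mri[t_min > ev_min & t_min <= ev_min + blackout_min] <- NA_real_
  }
  ranger$channels$MRI <- mri
  attr(ranger, "missing_fraction") <- mean(is.na(mri))
  ranger
}
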