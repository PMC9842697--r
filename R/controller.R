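#' Construct a pH probing schedule
#'
#' Ordered setpoint changes scheduled against fixed process times,
#' the pre-programmed ("scripted") probing mode.
#'
#' @param time_h strictly increasing change times, hours.
#' @param setpoint pH setpoints, within [5.5, 8.0].
#' @param label schedule label.
#' @param centre centre pH the schedule oscillates around (defaults to
#'   the mean setpoint); used for mirroring.
#' @return a `probe_schedule` (data.frame subclass).
#' @export
probe_schedule <- function(time_h, setpoint, label = "schedule",
                           centre = NULL) {
  if (length(time_h) != length(setpoint)) stop("length mismatch")
  if (any(diff(time_h) <= 0)) stop("schedule times must strictly increase")
  if (any(setpoint < 5.5 | setpoint > 8.0))
    stop("setpoints outside [5.5, 8.0]")
  out <- data.frame(time_h = time_h, setpoint = setpoint)
  attr(out, "label") <- label
  attr(out, "centre") <- centre %||% mean(setpoint)
  attr(out, "mirrored") <- FALSE
  class(out) <- c("probe_schedule", "data.frame")
  out
}

#' Mirror a probing schedule about its centre pH
#'
#' Returns the base schedule together with its reflection (each
#' excursion flipped about the centre, same times). Running both
#' profiles controls for the influence of prior cellular processing on
#' the pH-to-activity readout: mirror(mirror(x)) is x.
#'
#' @param base a `probe_schedule`.
#' @return list with `base` and `mirror`.
#' @export
make_mirrored_schedules <- function(base) {
  centre <- attr(base, "centre")
  mirror <- base
  mirror$setpoint <- 2 * centre - base$setpoint
  attr(mirror, "label") <- paste0(attr(base, "label"), "_mirror")
  attr(mirror, "mirrored") <- !attr(base, "mirrored")
  list(base = base, mirror = mirror)
}

## ---------------------------------------------------------------------------
## Light incremental plant used by the probing loops: pH lag + activity
## integral + PTI noise + MRI filter, advanced dwell by dwell. Must be
## driven inside one with_seed() stream for reproducibility.

.plant_init <- function(config) {
  list(config = config, t_min = 0, ph = config$ph_init, pti = 0)
}

.plant_step <- function(state, setpoint, minutes, blackout_min = 10) {
  cfg <- state$config
  n <- round(minutes)
  distorted <- stats::runif(1) < 0.2       # sluggish PID loop, seeded
  tau <- cfg$actuator_tau_min * if (distorted) 2 else 1
  ph <- numeric(n + 1L); ph[1] <- state$ph
  for (i in seq_len(n)) {
    if (abs(ph[i] - setpoint) > cfg$ph_deadband) {
      ph[i + 1L] <- actuate_ph(ph[i], setpoint, dt = 1, config = cfg,
                               tau_min = tau)
    } else {
      ph[i + 1L] <- max(ph[i] - cfg$drift_per_min, cfg$actuator_floor)
    }
  }
  dt_r <- cfg$ranger_period_s / 60
  t_rel <- seq(dt_r, n, by = dt_r)
  t_abs <- state$t_min + t_rel
  ph_r <- stats::approx(0:n, ph, xout = t_rel)$y
  act <- activity_response(ph_r, cfg) * .phase_mult(t_abs / 60, cfg)
  pti_true <- state$pti + cumsum(act * dt_r) +
    40 * (t_abs / 60 >= cfg$induction2_h &
            state$t_min / 60 < cfg$induction2_h)
  pti <- pti_true + stats::rnorm(length(pti_true), sd = cfg$noise_sigma_pti)
  mri <- compute_mri_vector(pti, dt_min = dt_r, params = mri_params())
  mri[t_rel <= blackout_min] <- NA_real_   # post-setpoint-change blackout
  list(state = list(config = cfg, t_min = state$t_min + n,
                    ph = ph[n + 1L], pti = pti_true[length(pti_true)]),
       t_min = t_abs, ph = ph_r, pti = pti, mri = mri)
}

#' Run a pre-programmed probing schedule against the simulated plant
#'
#' Issues the scheduled setpoints through the full simulator and logs,
#' at each change, the achieved pH and the trailing-window MRI
#' assessment.
#'
#' @param schedule a `probe_schedule`.
#' @param config a [sim_config()].
#' @param plant simulation hook with the [simulate_culture()] signature.
#' @param assess_min trailing MRI assessment window, minutes.
#' @return list with `log` (a `probe_log` data.frame) and `run` (the
#'   full simulator output).
#' @export
run_preprogrammed <- function(schedule, config = sim_config(),
                              plant = simulate_culture, assess_min = 30) {
  if (nrow(schedule) && max(schedule$time_h) >= config$duration_h)
    stop("schedule extends beyond the run duration")
  run <- plant(config, schedule)
  t_h <- run$truth$t_r_min / 60
  mri <- run$ranger$channels$MRI
  entries <- lapply(seq_len(nrow(schedule)), function(k) {
    ## assess over the dwell ending at the *next* change (or harvest)
    t_end <- if (k < nrow(schedule)) schedule$time_h[k + 1L] else
      config$duration_h
    win <- t_h > t_end - assess_min / 60 & t_h <= t_end
    i_ph <- which.min(abs(run$truth$t_min - t_end * 60))
    data.frame(time_h = schedule$time_h[k],
               setpoint = schedule$setpoint[k],
               achieved_ph = run$truth$ph_achieved[i_ph],
               mri_mean = mean(mri[win], na.rm = TRUE),
               direction = 0)
  })
  log <- if (length(entries)) do.call(rbind, entries) else
    data.frame(time_h = numeric(0), setpoint = numeric(0),
               achieved_ph = numeric(0), mri_mean = numeric(0),
               direction = numeric(0))
  class(log) <- c("probe_log", "data.frame")
  list(log = log, run = run)
}

#' Next setpoint of the autonomous probing rule
#'
#' The first adjustment is always downward; afterwards the rule repeats
#' the previous direction when the trailing-window MRI improved beyond
#' the tolerance and reverses it otherwise. Decisions work with the
#' achieved pH, not the commanded setpoint, and are clamped to bounds.
#' An all-missing MRI window (post-setpoint blackout) defers the
#' decision: the setpoint is held.
#'
#' @param history `probe_log` so far (0 rows before the first decision).
#' @param current_mri_window trailing MRI samples (may contain `NA`).
#' @param current_ph achieved pH at decision time.
#' @param step probing step, pH units (> 0).
#' @param bounds length-2 setpoint bounds.
#' @param improve_tol relative MRI improvement needed to call a move
#'   successful.
#' @return list with `setpoint`, `direction` (-1 down, +1 up, 0 hold)
#'   and `mri_mean`.
#' @export
autonomous_next_setpoint <- function(history, current_mri_window,
                                     current_ph, step,
                                     bounds = c(5.8, 7.4),
                                     improve_tol = 0.01) {
  if (step <= 0) stop("step must be positive")
  mri_mean <- if (length(current_mri_window) &&
                  any(!is.na(current_mri_window)))
    mean(current_mri_window, na.rm = TRUE) else NA_real_
  if (is.na(mri_mean) && nrow(history) > 0) {
    return(list(setpoint = history$setpoint[nrow(history)],
                direction = 0, mri_mean = NA_real_))
  }
  if (nrow(history) == 0) {
    dir <- -1
  } else {
    prev <- history[history$direction != 0 & !is.na(history$mri_mean), ]
    if (!nrow(prev)) {
      dir <- -1
    } else {
      prev_mri <- prev$mri_mean[nrow(prev)]
      prev_dir <- prev$direction[nrow(prev)]
      improved <- (mri_mean - prev_mri) > improve_tol * abs(prev_mri)
      dir <- if (improved) prev_dir else -prev_dir
    }
  }
  sp <- min(max(current_ph + dir * step, bounds[1]), bounds[2])
  list(setpoint = sp, direction = dir, mri_mean = mri_mean)
}

#' Autonomous MRI-driven pH probing run
#'
#' Closed loop against the simulated plant: from `start_h` the
#' controller periodically assesses the trailing-window MRI, compares
#' it with the previous dwell and adapts the pH setpoint by `step`
#' without any prior knowledge of the plant's activity optimum.
#'
#' @param config a [sim_config()] describing the plant.
#' @param init_ph initial setpoint held until probing starts.
#' @param start_h probing start, hours post inoculation.
#' @param step probing step, pH units.
#' @param dwell_min minutes between decisions.
#' @param bounds setpoint bounds.
#' @param assess_min trailing MRI assessment window, minutes.
#' @param blackout_min MRI blackout after each setpoint change, minutes.
#' @param improve_tol see [autonomous_next_setpoint()].
#' @return a `probe_log` with one row per decision plus attributes
#'   `terminal_setpoint` and `terminal_achieved_ph`.
#' @export
run_autonomous <- function(config = sim_config(ph_deadband = 0.02),
                           init_ph = 6.60, start_h = 26, step = 0.10,
                           dwell_min = 90, bounds = c(5.8, 7.4),
                           assess_min = 30, blackout_min = 10,
                           improve_tol = 0.01) {
  if (start_h >= config$duration_h) stop("probing starts after harvest")
  with_seed(config$seed, {
    state <- .plant_init(config)
    seg <- .plant_step(state, init_ph, start_h * 60,
                       blackout_min = blackout_min)
    state <- seg$state
    sp <- init_ph
    log <- data.frame(time_h = numeric(0), setpoint = numeric(0),
                      achieved_ph = numeric(0), mri_mean = numeric(0),
                      direction = numeric(0))
    while (state$t_min + dwell_min <= config$duration_h * 60) {
      n_assess <- round(assess_min / (config$ranger_period_s / 60))
      window <- utils::tail(seg$mri, n_assess)
      dec <- autonomous_next_setpoint(log, window, current_ph = state$ph,
                                      step = step, bounds = bounds,
                                      improve_tol = improve_tol)
      log <- rbind(log, data.frame(time_h = state$t_min / 60,
                                   setpoint = dec$setpoint,
                                   achieved_ph = state$ph,
                                   mri_mean = dec$mri_mean,
                                   direction = dec$direction))
      sp <- dec$setpoint
      seg <- .plant_step(state, sp, dwell_min, blackout_min = blackout_min)
      state <- seg$state
    }
    class(log) <- c("probe_log", "data.frame")
    attr(log, "terminal_setpoint") <- sp
    attr(log, "terminal_achieved_ph") <- state$ph
    log
  })
}

#' Decisions needed to come within a tolerance of a target pH
#'
#' Counts the probing decisions until the achieved pH first lies within
#' `tol` of `target` (e.g. the plant's activity optimum); `Inf` when
#' never reached.
#'
#' @param log a `probe_log`.
#' @param target target pH.
#' @param tol tolerance, pH units.
#' @export
probe_decisions_to_reach <- function(log, target, tol = 0.05) {
  hit <- which(abs(log$achieved_ph - target) <= tol + 1e-9)
  if (length(hit)) hit[1] else Inf
}
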