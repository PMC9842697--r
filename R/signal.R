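#' Parameters of the MRI derivation filter
#'
#' The metabolic rate index (MRI) is defined as the first derivative of
#' a second-order polynomial fitted locally to the raw PTI signal. The
#' window length is an instrument detail the analysis keeps
#' configurable; the polynomial order is fixed at 2 by definition.
#'
#' @param fit_window odd number of points per local fit (default 61,
#'   about 5 min at the 5 s probe period).
#' @param centered logical; `TRUE` fits centred windows (default),
#'   `FALSE` trailing (causal) windows, since the vendor filter's
#'   alignment is unspecified.
#' @return object of class `mri_params`.
#' @export
mri_params <- function(fit_window = 61, centered = TRUE) {
  fit_window <- as.integer(fit_window)
  if (fit_window < 5L || fit_window %% 2L == 0L)
    stop("fit_window must be odd and >= 5")
  structure(list(fit_window = fit_window, poly_order = 2L,
                 derivative_order = 1L, centered = centered),
            class = "mri_params")
}

## quadratic least-squares derivative at x0 over sample indices idx
.quad_deriv <- function(y, idx, j, dt) {
  x <- (idx - j) * dt
  X <- cbind(1, x, x^2)
  beta <- solve(crossprod(X), crossprod(X, y[idx]))
  beta[2]
}

#' Derive MRI from a PTI vector
#'
#' Core numeric kernel behind [compute_mri()]: local quadratic
#' least-squares fit per window, returning the analytic derivative of
#' the fit at the window centre (or trailing edge for causal windows),
#' in RU/min. Interior points use precomputed filter weights (for a
#' symmetric window the quadratic term is orthogonal to the linear one,
#' so the derivative reduces to the linear regression slope); edge
#' points shrink to one-sided windows.
#'
#' @param y numeric PTI samples, no missing values.
#' @param dt_min sampling interval in minutes.
#' @param params an [mri_params()].
#' @return numeric MRI vector of the same length.
#' @export
compute_mri_vector <- function(y, dt_min, params = mri_params()) {
  n <- length(y)
  p <- params$fit_window
  if (n < p) stop("series shorter than the fit window")
  if (anyNA(y)) stop("PTI input must not contain missing values")
  h <- (p - 1L) %/% 2L
  if (params$centered) {
    k <- -h:h
    w <- k / (sum(k^2) * dt_min)
    out <- stats::filter(y, rev(w), method = "convolution", sides = 2)
    out <- as.numeric(out)
    for (j in seq_len(h)) {
      out[j] <- .quad_deriv(y, 1:min(n, j + h), j, dt_min)
      jr <- n - j + 1L
      out[jr] <- .quad_deriv(y, max(1L, jr - h):n, jr, dt_min)
    }
  } else {
    x <- (-(p - 1L)):0 * dt_min
    X <- cbind(1, x, x^2)
    w <- solve(crossprod(X), t(X))[2, ]   # derivative at trailing point
    out <- as.numeric(stats::filter(y, rev(w), method = "convolution",
                                    sides = 1))
    for (j in seq_len(p - 1L))
      out[j] <- .quad_deriv(y, 1:max(3L, j), j, dt_min)
  }
  out
}

#' Derive the MRI channel of a PTI frame
#'
#' @param pti a [time_channel_frame()] holding a `PTI` channel (or the
#'   channel named by `channel`).
#' @param params an [mri_params()].
#' @param channel input channel name.
#' @return the frame with an `MRI` channel added/replaced.
#' @export
compute_mri <- function(pti, params = mri_params(), channel = "PTI") {
  y <- tcf_channel(pti, channel)
  dt_min <- pti$period_s / 60
  pti$channels$MRI <- compute_mri_vector(y, dt_min, params)
  pti
}

#' Condense a probe frame to the one-minute SCADA grid
#'
#' Each output minute is the arithmetic mean of that minute's
#' non-missing samples; a minute whose samples are all missing stays
#' missing. The result is alignable/mergeable with a SCADA frame.
#'
#' @param ranger probe `tcf` whose period divides 60 s.
#' @return minutely `tcf` with time in minutes.
#' @export
condense_to_minutely <- function(ranger) {
  if (60 %% ranger$period_s != 0)
    stop("probe period must divide 60 s")
  t_min <- ranger$time / if (ranger$time_unit == "s") 60 else 1
  minute <- floor(t_min + 1e-9)
  mins <- sort(unique(minute))
  cond <- lapply(ranger$channels, function(ch) {
    m <- tapply(ch, minute, function(v)
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
    as.numeric(m[as.character(mins)])
  })
  time_channel_frame(mins, cond, period_s = 60, time_unit = "min")
}

#' Univariate imputation of a gappy series
#'
#' Isolated single missing points are filled by a centred simple moving
#' average of the `k` nearest observed neighbours on each side;
#' contiguous missing sections are filled by Kalman smoothing on the
#' state-space representation of an automatically order-selected ARIMA
#' process fitted to the observed data (orders bounded at (2,1,2)).
#' Non-missing cells are never altered.
#'
#' @param series numeric vector with `NA` gaps.
#' @param single_gap_k neighbours per side for the moving average.
#' @param max_order ARIMA order bound `c(p, d, q)` for section gaps.
#' @return list with `series` (imputed) and `report` (an
#'   `imputation_report`: gap counts, missing fractions before/after,
#'   method per gap).
#' @export
impute_series <- function(series, single_gap_k = 2,
                          max_order = c(2, 1, 2)) {
  if (all(is.na(series))) stop("cannot impute an all-missing series")
  n <- length(series)
  miss_before <- mean(is.na(series))
  r <- rle(is.na(series))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  gaps <- data.frame(start = starts[r$values], length = r$lengths[r$values])
  out <- series
  methods <- character(nrow(gaps))

  singles <- which(gaps$length == 1L)
  for (g in singles) {
    j <- gaps$start[g]
    obs <- which(!is.na(series))
    left <- rev(obs[obs < j])[seq_len(single_gap_k)]
    right <- obs[obs > j][seq_len(single_gap_k)]
    nb <- c(left, right)
    out[j] <- mean(series[nb[!is.na(nb)]])
    methods[g] <- "sma"
  }

  sections <- which(gaps$length > 1L)
  if (length(sections)) {
    filled <- .kalman_impute(series, max_order = max_order)
    for (g in sections) {
      idx <- gaps$start[g]:(gaps$start[g] + gaps$length[g] - 1L)
      out[idx] <- filled$values[idx]
      methods[g] <- filled$method
    }
  }
  report <- structure(list(
    n_single_gaps = length(singles),
    n_section_gaps = length(sections),
    missing_fraction_before = miss_before,
    missing_fraction_after = mean(is.na(out)),
    gaps = cbind(gaps, method = methods)),
    class = "imputation_report")
  list(series = out, report = report)
}

#' @export
print.imputation_report <- function(x, ...) {
  cat(sprintf("<imputation_report: %d single + %d section gaps, missing %.1f%% -> %.1f%%>\n",
              x$n_single_gaps, x$n_section_gaps,
              100 * x$missing_fraction_before,
              100 * x$missing_fraction_after))
  invisible(x)
}

#' Gate a series on its missing-data fraction
#'
#' Series with extensive missingness - strictly more than the threshold
#' (default 15%) - are excluded from further analysis to avoid
#' imputation-related information gain or loss downstream.
#'
#' @param series numeric vector.
#' @param threshold maximal tolerated missing fraction.
#' @return list with `keep` (logical) and `fraction`.
#' @export
missingness_gate <- function(series, threshold = 0.15) {
  fraction <- mean(is.na(series))
  list(keep = fraction <= threshold, fraction = fraction)
}

#' PTI shift between two process times
#'
#' Difference of PTI at the end of the process and at the onset of
#' divergence between two control protocols (nearest-sample lookup);
#' the scalar metabolic-activity metric used to compare pH strategies.
#'
#' @param pti a `tcf` with a `PTI` channel, or a numeric vector with a
#'   `time_h` attribute.
#' @param t_divergence,t_end process times, hours, inside the series.
#' @param channel channel to read when `pti` is a frame.
#' @return PTI shift in RU.
#' @export
pti_shift <- function(pti, t_divergence, t_end, channel = "PTI") {
  if (inherits(pti, "tcf")) {
    t_h <- pti$time / if (pti$time_unit == "s") 3600 else 60
    y <- tcf_channel(pti, channel)
  } else {
    t_h <- attr(pti, "time_h")
    if (is.null(t_h)) stop("numeric input requires a 'time_h' attribute")
    y <- as.numeric(pti)
  }
  if (t_divergence >= t_end) stop("t_divergence must precede t_end")
  if (t_divergence < min(t_h) - 1e-9 || t_end > max(t_h) + 1e-9)
    stop("requested times outside the series")
  pick <- function(t0) y[which.min(abs(t_h - t0))]
  pick(t_end) - pick(t_divergence)
}

#' Specific growth rate from viable cell concentrations
#'
#' Two points give mu = ln(vcc2/vcc1)/(t2-t1); more points give the
#' least-squares slope of ln(VCC) against time.
#'
#' @param vcc viable cell concentrations (> 0), cells/mL.
#' @param time_h sample times, hours, strictly increasing.
#' @return mu in 1/h.
#' @export
specific_growth_rate <- function(vcc, time_h) {
  if (length(vcc) != length(time_h) || length(vcc) < 2)
    stop("need matching vcc/time vectors of length >= 2")
  if (any(vcc <= 0)) stop("VCC must be positive")
  if (any(diff(time_h) <= 0)) stop("times must be strictly increasing")
  if (length(vcc) == 2) {
    log(vcc[2] / vcc[1]) / (time_h[2] - time_h[1])
  } else {
    unname(stats::coef(stats::lm(log(vcc) ~ time_h))[2])
  }
}

#' Functional vector titre from a transduction assay
#'
#' Titre (TU/mL) = (percent parent-gated cells / 100 x cells at
#' transduction x dilution factor) / vector volume (mL).
#'
#' @param percent_parent GFP-positive (parent-gated) percentage, 0-100.
#' @param cells_at_transduction cell count prior to transduction.
#' @param dilution_factor fold dilution of the test sample.
#' @param volume_ml vector volume added, mL (> 0).
#' @return functional titre, TU/mL.
#' @export
functional_titre <- function(percent_parent, cells_at_transduction,
                             dilution_factor, volume_ml) {
  if (volume_ml <= 0) stop("volume must be positive")
  if (percent_parent < 0 || percent_parent > 100)
    stop("percent_parent must be within [0, 100]")
  (percent_parent / 100 * cells_at_transduction * dilution_factor) /
    volume_ml
}

#' Total lentiviral particles from a p24 measurement
#'
#' Total particles/mL = (p24 concentration / p24 molecular weight) x
#' (Avogadro's number / p24 molecules per particle), with molecular
#' weight 2.4e4 and 2000 p24 molecules per particle.
#'
#' @param p24_g_per_ml p24 capsid concentration, g/mL (>= 0).
#' @return particles/mL.
#' @export
total_particles <- function(p24_g_per_ml) {
  if (any(p24_g_per_ml < 0)) stop("p24 concentration cannot be negative")
  (p24_g_per_ml / 2.4e4) * (6.022e23 / 2000)
}
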