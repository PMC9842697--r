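#' Uniformly sampled multichannel time series
#'
#' The lingua franca of all signal stages: a strictly increasing,
#' uniformly spaced time axis (elapsed process time) plus named numeric
#' channels of equal length. Missing values are representable per cell
#' as `NA`.
#'
#' @param time numeric elapsed-process-time stamps.
#' @param channels named list or data.frame of numeric channels.
#' @param period_s sampling period in seconds.
#' @param time_unit `"min"` (SCADA convention) or `"s"` (in-situ probe
#'   convention).
#' @return object of class `tcf` (time-channel frame).
#' @export
time_channel_frame <- function(time, channels, period_s,
                               time_unit = c("min", "s")) {
  time_unit <- match.arg(time_unit)
  channels <- as.data.frame(channels, optional = TRUE)
  if (nrow(channels) != length(time))
    stop("channels and timestamps differ in length")
  step <- period_s / if (time_unit == "min") 60 else 1
  if (length(time) > 1) {
    d <- diff(time)
    if (any(d <= 0)) stop("timestamps must be strictly increasing")
    if (max(abs(d - step)) > 1e-6 * step)
      stop("timestamps are not uniformly spaced at the stated period")
  }
  structure(list(time = as.numeric(time), channels = channels,
                 period_s = period_s, time_unit = time_unit),
            class = "tcf")
}

#' @export
print.tcf <- function(x, ...) {
  cat(sprintf("<tcf: %d samples x %d channels, period %gs, time in %s>\n",
              length(x$time), ncol(x$channels), x$period_s, x$time_unit))
  cat("channels:", paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.tcf <- function(x, ...) {
  tcol <- if (x$time_unit == "min") "ept_min" else "ept_s"
  out <- cbind(stats::setNames(data.frame(x$time), tcol), x$channels)
  out
}

#' Number of samples in a frame
#' @param x a `tcf`.
#' @export
tcf_length <- function(x) length(x$time)

#' Extract one channel as a numeric vector
#' @param x a `tcf`.
#' @param channel channel name.
#' @export
tcf_channel <- function(x, channel) {
  if (!channel %in% names(x$channels)) stop("unknown channel: ", channel)
  x$channels[[channel]]
}

#' Write / read a frame as CSV
#'
#' Header row holds `ept_min` (or `ept_s`) followed by one column per
#' channel; empty cells encode missing values.
#' @param x a `tcf`.
#' @param path CSV path.
#' @export
write_frame_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_frame_csv
#' @param period_s sampling period of the stored frame, seconds; inferred
#'   from the time column when `NULL`.
#' @export
read_frame_csv <- function(path, period_s = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  tcol <- names(df)[1]
  unit <- if (tcol == "ept_s") "s" else "min"
  time <- df[[1]]
  if (is.null(period_s)) {
    step <- if (length(time) > 1) time[2] - time[1] else 1
    period_s <- step * if (unit == "min") 60 else 1
  }
  time_channel_frame(time, df[-1], period_s = period_s, time_unit = unit)
}

#' Merge a condensed probe frame into a SCADA frame
#'
#' Joins on the minute grid; only overlapping minutes are kept.
#' @param scada,probe `tcf` objects on a 60 s period with time in
#'   minutes.
#' @export
merge_frames <- function(scada, probe) {
  if (scada$period_s != probe$period_s)
    stop("frames must share a sampling period")
  common <- intersect(round(scada$time, 6), round(probe$time, 6))
  i <- match(common, round(scada$time, 6))
  j <- match(common, round(probe$time, 6))
  keep <- setdiff(names(probe$channels), names(scada$channels))
  time_channel_frame(scada$time[i],
                     cbind(scada$channels[i, , drop = FALSE],
                           probe$channels[j, keep, drop = FALSE]),
                     period_s = scada$period_s,
                     time_unit = scada$time_unit)
}
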