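#' EDA recording container
#'
#' An `eda_recording` holds a uniformly sampled skin-conductance trace in
#' microsiemens together with its sampling rate. It is the common currency of
#' all I/O and preprocessing functions in the package.
#'
#' @param samples Numeric vector of conductance values (uS). Must be finite
#'   and non-empty.
#' @param rate Sampling frequency in Hz (default 8, the rate used by research
#'   wearables for EDA).
#' @param start_time Time offset of the first sample in seconds (default 0).
#' @return An object of class `eda_recording`.
#' @examples
#' rec <- eda_recording(rep(1.5, 1440), rate = 8)
#' duration(rec)
#' @export
eda_recording <- function(samples, rate = 8, start_time = 0) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L)
    stop("an EDA recording needs at least one sample", call. = FALSE)
  if (!all(is.finite(samples)))
    stop("EDA samples must all be finite", call. = FALSE)
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("sampling rate must be a positive number (Hz)", call. = FALSE)
  structure(
    list(samples = samples, rate = rate, start_time = start_time),
    class = "eda_recording"
  )
}

#' @export
print.eda_recording <- function(x, ...) {
  cat(sprintf("<eda_recording> %d samples @ %g Hz (%.1f s), %.3f-%.3f uS\n",
              length(x$samples), x$rate, duration(x),
              min(x$samples), max(x$samples)))
  invisible(x)
}

#' @export
length.eda_recording <- function(x) length(x$samples)

#' Duration of a recording or frame in seconds
#' @param x An `eda_recording` or `eda_frame`.
#' @return Duration in seconds.
#' @export
duration <- function(x) UseMethod("duration")

#' @export
duration.eda_recording <- function(x) length(x$samples) / x$rate

#' @export
duration.eda_frame <- function(x) length(x$samples) / x$rate

#' Analysis frame
#'
#' A fixed-duration window of an EDA recording; the unit on which every
#' decomposition method operates. The canonical frame is 180 s at 8 Hz
#' (1440 samples); shorter frames are permitted for small-scale experiments
#' but the sample count must always equal `rate * duration_s` exactly.
#'
#' @param samples Numeric vector of conductance values (uS).
#' @param rate Sampling rate in Hz.
#' @param duration_s Frame duration in seconds; defaults to
#'   `length(samples) / rate` and is cross-checked against it.
#' @return An object of class `eda_frame`.
#' @export
eda_frame <- function(samples, rate = 8, duration_s = length(samples) / rate) {
  samples <- as.numeric(samples)
  if (!all(is.finite(samples)))
    stop("frame samples must all be finite", call. = FALSE)
  n <- length(samples)
  if (n < 2L) stop("a frame needs at least two samples", call. = FALSE)
  if (abs(n - rate * duration_s) > 1e-8)
    stop(sprintf("frame length %d != rate %g Hz x duration %g s", n, rate,
                 duration_s), call. = FALSE)
  structure(list(samples = samples, rate = rate, duration = duration_s),
            class = "eda_frame")
}

#' @export
print.eda_frame <- function(x, ...) {
  cat(sprintf("<eda_frame> %d samples @ %g Hz (%g s)\n",
              length(x$samples), x$rate, x$duration))
  invisible(x)
}

#' @export
length.eda_frame <- function(x) length(x$samples)

#' Read an EDA trace from CSV
#'
#' Expects two columns, `time_s` (seconds) and `eda_us` (microsiemens), with
#' strictly increasing, uniformly spaced timestamps. The sampling rate is
#' inferred from the median timestamp increment; files whose timestamps
#' deviate from that increment by more than 1% are rejected rather than
#' silently resampled.
#'
#' @param path Path to a CSV file with header `time_s,eda_us`.
#' @return An [eda_recording].
#' @export
read_eda_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  if (nrow(df) == 0L)
    stop("empty EDA file: ", path, call. = FALSE)
  if (ncol(df) < 2L)
    stop("expected two columns (time_s, eda_us) in ", path, call. = FALSE)
  t <- as.numeric(df[[1L]])
  y <- as.numeric(df[[2L]])
  if (anyNA(t) || anyNA(y))
    stop("non-numeric values in ", path, call. = FALSE)
  if (length(t) < 2L)
    stop("need at least two samples to infer a sampling rate", call. = FALSE)
  dt <- diff(t)
  if (any(dt <= 0))
    stop("timestamps must be strictly increasing in ", path, call. = FALSE)
  step <- stats::median(dt)
  if (max(abs(dt - step)) > 0.01 * step)
    stop("irregular timestamps (>1% jitter); refusing to infer a rate",
         call. = FALSE)
  eda_recording(y, rate = 1 / step, start_time = t[1L])
}

#' Write an EDA trace to CSV
#'
#' @param rec An [eda_recording].
#' @param path Output path; written with header `time_s,eda_us`.
#' @export
write_eda_csv <- function(rec, path) {
  stopifnot(inherits(rec, "eda_recording"))
  t <- rec$start_time + (seq_along(rec$samples) - 1) / rec$rate
  utils::write.csv(data.frame(time_s = t, eda_us = rec$samples), path,
                   row.names = FALSE)
  invisible(path)
}

#' Low-pass filter specification
#'
#' Butterworth low-pass design used to clean raw EDA before framing. The
#' defaults (3 Hz cutoff, 4th order) pass all EDA-relevant content --
#' skin-conductance responses live well below 3 Hz -- while removing sensor
#' noise near the Nyquist frequency.
#'
#' @param cutoff Cutoff frequency in Hz (default 3).
#' @param order Filter order (default 4).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(cutoff = 3, order = 4) {
  if (!is.numeric(cutoff) || cutoff <= 0)
    stop("cutoff must be positive (Hz)", call. = FALSE)
  if (order < 1 || order != round(order))
    stop("order must be a positive integer", call. = FALSE)
  structure(list(cutoff = cutoff, order = as.integer(order), kind = "low"),
            class = "filter_spec")
}

#' Zero-phase low-pass filtering of an EDA recording
#'
#' Applies the Butterworth design forward and backward (`signal::filtfilt`),
#' giving zero phase distortion so SCR onsets are not shifted in time. The
#' output has the same length and rate as the input.
#'
#' @param rec An [eda_recording].
#' @param spec A [filter_spec]; cutoff must lie below the Nyquist frequency.
#' @return Filtered [eda_recording].
#' @export
lowpass_filter <- function(rec, spec = filter_spec()) {
  stopifnot(inherits(rec, "eda_recording"), inherits(spec, "filter_spec"))
  nyquist <- rec$rate / 2
  if (spec$cutoff >= nyquist)
    stop(sprintf("cutoff %g Hz must be below the Nyquist frequency %g Hz",
                 spec$cutoff, nyquist), call. = FALSE)
  bf <- signal::butter(spec$order, spec$cutoff / nyquist, type = "low")
  # filtfilt needs some run-in; reflect-pad to suppress edge transients
  x <- rec$samples
  n <- length(x)
  pad <- min(n - 1L, 3L * (spec$order + 1L) * 8L)
  if (pad > 0L) {
    xp <- c(2 * x[1L] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
    yp <- signal::filtfilt(bf, xp)
    y <- yp[(pad + 1L):(pad + n)]
  } else {
    y <- signal::filtfilt(bf, x)
  }
  eda_recording(y, rate = rec$rate, start_time = rec$start_time)
}

#' Cut a recording into non-overlapping frames
#'
#' Consecutive, non-overlapping windows of `frame_seconds`; an incomplete
#' trailing window is discarded (padding would bias the tonic-slope
#' statistic computed per frame).
#'
#' @param rec An [eda_recording].
#' @param frame_seconds Frame duration in seconds (default 180).
#' @return List of [eda_frame] objects.
#' @export
frame_signal <- function(rec, frame_seconds = 180) {
  stopifnot(inherits(rec, "eda_recording"))
  n_per <- round(rec$rate * frame_seconds)
  if (abs(n_per - rec$rate * frame_seconds) > 1e-8)
    stop("frame_seconds must give an integer number of samples", call. = FALSE)
  n <- length(rec$samples)
  k <- n %/% n_per
  if (k < 1L)
    stop(sprintf("recording too short: %d samples < one %g s frame (%d)",
                 n, frame_seconds, n_per), call. = FALSE)
  lapply(seq_len(k), function(i) {
    eda_frame(rec$samples[((i - 1L) * n_per + 1L):(i * n_per)],
              rate = rec$rate, duration_s = frame_seconds)
  })
}

#' Resample a recording by linear interpolation
#'
#' Places a new uniform grid over the same time span and interpolates
#' linearly. SCR content is band-limited well below the rates involved
#' (8-24 Hz), so linear interpolation is adequate and artifact-free.
#'
#' @param rec An [eda_recording].
#' @param target_rate New sampling rate in Hz.
#' @return Resampled [eda_recording] spanning the same duration.
#' @export
resample_eda <- function(rec, target_rate) {
  stopifnot(inherits(rec, "eda_recording"))
  if (!is.numeric(target_rate) || target_rate <= 0)
    stop("target_rate must be positive", call. = FALSE)
  if (isTRUE(all.equal(target_rate, rec$rate)))
    return(rec)
  dur <- duration(rec)
  t_old <- (seq_along(rec$samples) - 1) / rec$rate
  n_new <- floor(dur * target_rate + 1e-9)
  t_new <- (seq_len(n_new) - 1) / target_rate
  y <- stats::approx(t_old, rec$samples, xout = t_new, rule = 2)$y
  # continue the boundary slope for grid points beyond the last input
  # sample, so lines resample to lines over the full duration
  n_old <- length(rec$samples)
  if (n_old >= 2L) {
    tail_idx <- which(t_new > t_old[n_old])
    if (length(tail_idx)) {
      slope <- (rec$samples[n_old] - rec$samples[n_old - 1L]) * rec$rate
      y[tail_idx] <- rec$samples[n_old] + slope * (t_new[tail_idx] -
                                                     t_old[n_old])
    }
  }
  eda_recording(y, rate = target_rate, start_time = rec$start_time)
}

#' Write a per-frame decomposition to CSV
#'
#' Emits the standard four-column decomposition table
#' `time_s,eda_us,tonic_us,phasic_us`.
#'
#' @param frame The decomposed [eda_frame].
#' @param decomp An [eda_decomposition] for that frame.
#' @param path Output CSV path.
#' @export
write_decomposition_csv <- function(frame, decomp, path) {
  stopifnot(inherits(frame, "eda_frame"), inherits(decomp, "eda_decomposition"))
  t <- (seq_along(frame$samples) - 1) / frame$rate
  utils::write.csv(
    data.frame(time_s = t, eda_us = frame$samples,
               tonic_us = decomp$tonic, phasic_us = decomp$phasic),
    path, row.names = FALSE)
  invisible(path)
}
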