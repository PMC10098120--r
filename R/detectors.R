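# The two component detectors of the fusion pipeline: complex Morlet wavelet
# envelope thresholding and small-window RMS thresholding. Both use relative
# (data-driven) thresholds per channel over the scoring window, so detection
# is invariant to overall signal scaling and DC offset.

#' Default detector parameters
#'
#' Numeric operating points of the two detectors (the detector families are
#' fixed; all values are tunable through the config):
#' wavelet: 13.5 Hz centre, 7 cycles, 0.1 s envelope smoothing, threshold at
#' 2x the median envelope; RMS: 0.25 s windows stepping 0.1 s, threshold at
#' the 95th percentile; both: 0.2 s gap merge, durations kept in
#' `[0.5, 3.0]` s.
#'
#' @param config optional config list (see [default_config()]).
#' @return flat named list of detector parameters.
#' @export
detector_params <- function(config = default_config()) {
  list(
    band_low_hz = config$band$low_hz, band_high_hz = config$band$high_hz,
    center_freq_hz = config$wavelet$center_freq_hz,
    n_cycles = config$wavelet$n_cycles,
    smooth_win_s = config$wavelet$smooth_win_s,
    threshold_multiplier = config$wavelet$threshold_multiplier,
    window_s = config$rms$window_s, step_s = config$rms$step_s,
    percentile = config$rms$percentile, merge_gap_s = config$rms$merge_gap_s,
    min_dur_s = config$duration$min_s, max_dur_s = config$duration$max_s
  )
}

# FFT-based "same" convolution of a real signal with a complex kernel.
conv_same <- function(x, kernel) {
  nx <- length(x)
  nk <- length(kernel)
  nfft <- stats::nextn(nx + nk - 1, 2)
  X <- stats::fft(c(x, rep(0, nfft - nx)))
  K <- stats::fft(c(kernel, rep(0+0i, nfft - nk)))
  full <- stats::fft(X * K, inverse = TRUE) / nfft
  start <- floor(nk / 2)
  full[(start + 1):(start + nx)]
}

moving_average <- function(x, width) {
  if (width <= 1) return(x)
  k <- rep(1 / width, width)
  n <- length(x)
  pad <- floor(width / 2)
  xp <- c(rep(x[1], pad), x, rep(x[n], width - pad - 1))
  as.numeric(stats::filter(xp, k, method = "convolution", sides = 1)[width:(width + n - 1)])
}

#' Morlet wavelet envelope of a signal
#'
#' Magnitude of the convolution with a complex Morlet wavelet (Gaussian
#' envelope, `n_cycles` cycles at the centre frequency), smoothed by a short
#' moving average. For sigma-band bursts the envelope rises above the
#' background's median level, which is what [detect_wavelet()] thresholds.
#'
#' @param signal numeric vector (raw EEG, microvolts).
#' @param rate sampling rate in Hz.
#' @param params detector parameter list (see [detector_params()]).
#' @return list with `values` (non-negative envelope, same length as input),
#'   `rate`, `t0_s`.
#' @export
morlet_envelope <- function(signal, rate, params = detector_params()) {
  f0 <- params$center_freq_hz
  sigma_t <- params$n_cycles / (2 * pi * f0)
  half <- ceiling(3.5 * sigma_t * rate)
  if (length(signal) < 2 * half + 1) {
    stop("signal shorter than one wavelet support (", 2 * half + 1, " samples)")
  }
  tt <- seq(-half, half) / rate
  kernel <- exp(2i * pi * f0 * tt) * exp(-tt^2 / (2 * sigma_t^2))
  kernel <- kernel / sum(Mod(kernel))          # unit-l1 so envelope ~ amplitude
  env <- Mod(conv_same(signal - mean(signal), kernel))
  env <- moving_average(env, max(1, round(params$smooth_win_s * rate)))
  list(values = env, rate = rate, t0_s = 0)
}

# Threshold-crossing runs -> events: maximal runs of `values > threshold`
# (times are sample/window centres spaced 1/rate), half-sample extended to
# intervals, gap-merged, then duration-filtered.
runs_to_events <- function(values, times, threshold, half_width_s,
                           merge_gap_s, min_dur_s, max_dur_s,
                           channel, source) {
  above <- values > threshold
  if (!any(above)) return(empty_events())
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  onset <- times[starts[keep]] - half_width_s
  offset <- times[ends[keep]] + half_width_s

  # merge runs separated by less than merge_gap_s
  if (length(onset) > 1) {
    merged_on <- onset[1]; merged_off <- offset[1]
    out_on <- numeric(); out_off <- numeric()
    for (i in seq(2, length(onset))) {
      if (onset[i] - merged_off < merge_gap_s) {
        merged_off <- max(merged_off, offset[i])
      } else {
        out_on <- c(out_on, merged_on); out_off <- c(out_off, merged_off)
        merged_on <- onset[i]; merged_off <- offset[i]
      }
    }
    onset <- c(out_on, merged_on); offset <- c(out_off, merged_off)
  }

  dur <- offset - onset
  keep <- dur >= min_dur_s & dur <= max_dur_s
  if (!any(keep)) return(empty_events())
  spindle_events(channel = channel, onset_s = onset[keep],
                 offset_s = offset[keep], source = source)
}

#' Detect spindles by Morlet-wavelet envelope thresholding
#'
#' Events are maximal runs where the envelope exceeds
#' `threshold_multiplier x median(envelope)` within the scoring window; runs
#' closer than the merge gap are joined, and only events with duration in
#' `[min_dur_s, max_dur_s]` are kept.
#'
#' @inheritParams morlet_envelope
#' @param channel channel label to stamp on the events.
#' @param window optional [scoring_window()]; detection and the median
#'   threshold are restricted to it.
#' @return an `event_set` with `source = "wavelet"`.
#' @export
detect_wavelet <- function(signal, rate, params = detector_params(),
                           channel = "C3", window = NULL) {
  env <- morlet_envelope(signal, rate, params)
  values <- env$values
  times <- (seq_along(values) - 1) / rate
  if (!is.null(window)) {
    sel <- times >= window$start_s & times < window$end_s
    values <- values[sel]; times <- times[sel]
  }
  med <- stats::median(values)
  if (med <= 0) return(empty_events())
  runs_to_events(values, times, params$threshold_multiplier * med,
                 half_width_s = 0.5 / rate,
                 merge_gap_s = params$merge_gap_s,
                 min_dur_s = params$min_dur_s, max_dur_s = params$max_dur_s,
                 channel = channel, source = "wavelet")
}

#' Sliding-window RMS series
#'
#' Root mean square over windows of `window_s` advancing by `step_s`;
#' timestamps are window centres.
#'
#' @param filtered_signal sigma-band-passed signal.
#' @param rate sampling rate in Hz.
#' @param window_s,step_s window and hop sizes in seconds.
#' @return list with `values`, `rate` (= 1/step), `t0_s` (first window
#'   centre).
#' @export
rms_series <- function(filtered_signal, rate, window_s = 0.25, step_s = 0.1) {
  wlen <- max(1L, round(window_s * rate))
  step <- max(1L, round(step_s * rate))
  n <- length(filtered_signal)
  if (wlen > n) stop("RMS window longer than signal")
  starts <- seq(1L, n - wlen + 1L, by = step)
  csum <- c(0, cumsum(filtered_signal^2))
  values <- sqrt((csum[starts + wlen] - csum[starts]) / wlen)
  list(values = values, rate = rate / step,
       t0_s = (starts[1] - 1 + (wlen - 1) / 2) / rate,
       step_s = step / rate, window_s = wlen / rate)
}

#' Detect spindles by small-window RMS thresholding
#'
#' Band-passes the signal to the sigma band, computes the sliding-window RMS,
#' and keeps maximal runs exceeding the configured percentile of the series
#' over the scoring window; gap-merge and duration-filter as in
#' [detect_wavelet()].
#'
#' @inheritParams detect_wavelet
#' @return an `event_set` with `source = "rms"`.
#' @export
detect_rms <- function(signal, rate, params = detector_params(),
                       channel = "C3", window = NULL) {
  filtered <- bandpass(signal, rate, params$band_low_hz, params$band_high_hz)
  rs <- rms_series(filtered, rate, params$window_s, params$step_s)
  times <- rs$t0_s + (seq_along(rs$values) - 1) * rs$step_s
  values <- rs$values
  if (!is.null(window)) {
    sel <- times >= window$start_s & times < window$end_s
    values <- values[sel]; times <- times[sel]
  }
  if (length(values) == 0 || all(values == 0)) return(empty_events())
  threshold <- stats::quantile(values, params$percentile / 100, names = FALSE)
  runs_to_events(values, times, threshold,
                 half_width_s = rs$window_s / 2,
                 merge_gap_s = params$merge_gap_s,
                 min_dur_s = params$min_dur_s, max_dur_s = params$max_dur_s,
                 channel = channel, source = "rms")
}
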