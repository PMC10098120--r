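# Spindle characteristics: density per minute, max peak-to-peak amplitude of
# the sigma-band-passed event segment, FFT mean frequency, fixed-bin frequency
# and amplitude histograms, and symmetric-channel counts.

FREQ_BREAKS <- c(11, 12, 13, 14, 15, 16)
AMP_BREAKS <- c(0, 10, 20, 30, 40, 50, 60, 70, Inf)

#' Spindle density
#'
#' Number of spindles per minute of sleep. Whole-night analyses use the fixed
#' 480 min (8 h) scoring denominator; first-cycle analyses use the actual
#' first-cycle minutes.
#'
#' @param n_spindles event count.
#' @param minutes denominator in minutes (> 0).
#' @return events per minute.
#' @export
spindle_density <- function(n_spindles, minutes) {
  if (any(minutes <= 0)) stop("minutes must be positive")
  n_spindles / minutes
}

# Extract an event's samples plus `pad_s` context on each side; errors if the
# event lies outside the recording.
event_segment <- function(recording, channel, onset_s, offset_s, pad_s = 0) {
  if (!channel %in% recording$channel_labels) {
    stop("channel ", channel, " not in recording")
  }
  x <- recording$samples[[channel]]
  rate <- recording$sampling_rate
  dur <- length(x) / rate
  rel_on <- onset_s - recording$start_offset_s
  rel_off <- offset_s - recording$start_offset_s
  if (rel_on < 0 || rel_off > dur) {
    stop(sprintf("event [%.2f, %.2f) outside recording (0-%.2f s)",
                 onset_s, offset_s, dur))
  }
  i0 <- max(1L, time_to_index(rel_on - pad_s, rate))
  i1 <- min(length(x), time_to_index(rel_off + pad_s, rate) - 1L)
  list(samples = x[i0:i1], rate = rate,
       ev_start = time_to_index(rel_on, rate) - i0 + 1L,
       ev_end = min(i1, time_to_index(rel_off, rate) - 1L) - i0 + 1L)
}

#' Maximum peak-to-peak amplitude of one event
#'
#' The event's samples are band-passed to 11-16 Hz (with 0.5 s context on
#' each side to absorb filter edge effects) and the max minus min over the
#' event interval is returned, in microvolts.
#'
#' @param recording an [eeg_recording()].
#' @param channel,onset_s,offset_s the event.
#' @return peak-to-peak amplitude in microvolts.
#' @export
amplitude_pp <- function(recording, channel, onset_s, offset_s) {
  seg <- event_segment(recording, channel, onset_s, offset_s, pad_s = 0.5)
  filtered <- bandpass(seg$samples, seg$rate, SIGMA_BAND[1], SIGMA_BAND[2])
  ev <- filtered[seg$ev_start:seg$ev_end]
  max(ev) - min(ev)
}

#' Mean frequency of one event by FFT
#'
#' Detrended, Hann-windowed periodogram of the event segment, zero-padded to
#' 4 s (0.25 Hz resolution); the mean frequency is the power-weighted average
#' over the 11-16 Hz band.
#'
#' @inheritParams amplitude_pp
#' @return mean frequency in Hz, inside `[11, 16]`.
#' @export
mean_frequency <- function(recording, channel, onset_s, offset_s) {
  if (offset_s - onset_s < 0.5) stop("event shorter than 0.5 s")
  seg <- event_segment(recording, channel, onset_s, offset_s, pad_s = 0)
  x <- seg$samples[seg$ev_start:seg$ev_end]
  n <- length(x)
  x <- stats::residuals(stats::lm.fit(cbind(1, seq_len(n)), x))  # detrend
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))         # Hann
  x <- x * w
  nfft <- max(n, round(4 * seg$rate))
  spec <- Mod(stats::fft(c(x, rep(0, nfft - n))))^2
  freqs <- (seq_len(nfft) - 1) * seg$rate / nfft
  band <- freqs >= SIGMA_BAND[1] & freqs <= SIGMA_BAND[2]
  p <- spec[band]
  if (sum(p) == 0) return(mean(SIGMA_BAND))
  sum(freqs[band] * p) / sum(p)
}

#' Compute amplitude and frequency features for every event
#'
#' @param recording an [eeg_recording()].
#' @param events an `event_set` whose events lie within the recording.
#' @return the event set with `amplitude_pp_uV` and `mean_freq_hz` filled in.
#' @export
event_features <- function(recording, events) {
  if (nrow(events) == 0) return(events)
  for (i in seq_len(nrow(events))) {
    events$amplitude_pp_uV[i] <- amplitude_pp(
      recording, events$channel[i], events$onset_s[i], events$offset_s[i])
    events$mean_freq_hz[i] <- mean_frequency(
      recording, events$channel[i], events$onset_s[i], events$offset_s[i])
  }
  validate_events(events)
}

#' Frequency and amplitude histograms over the field's fixed bins
#'
#' Frequency: five 1 Hz bands over 11-16 Hz (left-closed, last band closed).
#' Amplitude: eight 10 uV bins from 0 with the last open-ended. Proportions
#' sum to 1 for non-empty input; all-zero histograms for empty input.
#'
#' @param mean_freq_hz,amplitude_pp_uV per-event feature vectors.
#' @return list with `frequency` and `amplitude` named proportion vectors and
#'   the event count `n`.
#' @export
spindle_histograms <- function(mean_freq_hz, amplitude_pp_uV) {
  freq_labels <- c("[11,12)", "[12,13)", "[13,14)", "[14,15)", "[15,16]")
  amp_labels <- c("[0,10)", "[10,20)", "[20,30)", "[30,40)", "[40,50)",
                  "[50,60)", "[60,70)", "[70,Inf)")
  n <- length(mean_freq_hz)
  if (n == 0) {
    return(list(frequency = stats::setNames(rep(0, 5), freq_labels),
                amplitude = stats::setNames(rep(0, 8), amp_labels), n = 0L))
  }
  fcut <- cut(mean_freq_hz, FREQ_BREAKS, right = FALSE, include.lowest = TRUE)
  fcut[mean_freq_hz == 16] <- levels(fcut)[5]   # [15,16] closed on the right
  acut <- cut(amplitude_pp_uV, AMP_BREAKS, right = FALSE)
  list(frequency = stats::setNames(as.numeric(table(fcut)) / n, freq_labels),
       amplitude = stats::setNames(as.numeric(table(acut)) / n, amp_labels),
       n = n)
}

#' Spindle counts in symmetric channel pairs
#'
#' Compares event counts between homologous left/right channels (C3/C4
#' central, F3/F4 frontal by default) and reports the signed difference
#' (right minus left).
#'
#' @param events an `event_set` spanning the channels.
#' @param pairs list of 2-vectors of channel labels.
#' @param channels the recorded channel universe; a pair member outside it is
#'   an error, while a recorded channel with zero events simply counts 0.
#'   Defaults to the channels seen in `events`.
#' @return data frame with columns `left`, `right`, `n_left`, `n_right`,
#'   `difference`.
#' @export
symmetric_counts <- function(events,
                             pairs = list(c("C3", "C4"), c("F3", "F4")),
                             channels = NULL) {
  present <- if (is.null(channels)) unique(events$channel) else channels
  rows <- lapply(pairs, function(p) {
    if (!all(p %in% present)) {
      stop("symmetric pair ", p[1], "/", p[2], ": channel(s) missing from events")
    }
    nl <- sum(events$channel == p[1])
    nr <- sum(events$channel == p[2])
    data.frame(left = p[1], right = p[2], n_left = nl, n_right = nr,
               difference = nr - nl, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-subject, per-channel feature summary
#'
#' @param recording an [eeg_recording()].
#' @param events detected events with features (computed when absent).
#' @param minutes density denominator in minutes (480 for whole night).
#' @return data frame, one row per channel, with count, density, mean
#'   amplitude, mean frequency and the histogram proportions.
#' @export
feature_summary <- function(recording, events, minutes = 480) {
  if (nrow(events) > 0 && anyNA(events$amplitude_pp_uV)) {
    events <- event_features(recording, events)
  }
  chans <- unique(events$channel)
  if (length(chans) == 0) chans <- recording$channel_labels
  rows <- lapply(chans, function(ch) {
    ev <- events[events$channel == ch, , drop = FALSE]
    h <- spindle_histograms(ev$mean_freq_hz, ev$amplitude_pp_uV)
    cbind(
      data.frame(subject_id = recording$subject_id, channel = ch,
                 n_spindles = nrow(ev),
                 density_per_min = spindle_density(nrow(ev), minutes),
                 mean_amplitude_uV = if (nrow(ev)) mean(ev$amplitude_pp_uV) else NA_real_,
                 mean_frequency_hz = if (nrow(ev)) mean(ev$mean_freq_hz) else NA_real_,
                 stringsAsFactors = FALSE),
      as.data.frame(t(c(h$frequency, h$amplitude)))
    )
  })
  do.call(rbind, rows)
}
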