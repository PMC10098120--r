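#' Construct a set of spindle events
#'
#' An event set is the package's central container: a data frame with one row
#' per detected or annotated spindle, ordered by onset within each channel.
#' Intervals are half-open `[onset_s, offset_s)` in seconds from recording
#' start, so touching events do not overlap and every time point belongs to at
#' most one event per detector run.
#'
#' @param channel character vector of 10-20-system channel labels (C3, C4, ...).
#' @param onset_s,offset_s numeric vectors, event boundaries in seconds.
#' @param amplitude_pp_uV optional numeric, max peak-to-peak amplitude in
#'   microvolts of the 11-16 Hz band-passed segment (`NA` before feature
#'   extraction).
#' @param mean_freq_hz optional numeric, power-weighted mean frequency in Hz
#'   (`NA` before feature extraction).
#' @param source provenance of each event: one of `"wavelet"`, `"rms"`,
#'   `"fusion"`, `"expert"`, `"truth"`.
#' @param label truth label: `"true"`, `"false"` or `"unknown"`.
#' @return a validated `event_set` data frame (sorted per channel, duplicate
#'   channel+interval rows removed).
#' @seealso [validate_events()], [event_duration()], [events_overlap()]
#' @export
spindle_events <- function(channel = character(), onset_s = numeric(),
                           offset_s = numeric(), amplitude_pp_uV = NA_real_,
                           mean_freq_hz = NA_real_, source = "truth",
                           label = "unknown") {
  n <- length(onset_s)
  df <- data.frame(
    channel = rep_len(as.character(channel), n),
    onset_s = as.numeric(onset_s),
    offset_s = as.numeric(offset_s),
    amplitude_pp_uV = rep_len(as.numeric(amplitude_pp_uV), n),
    mean_freq_hz = rep_len(as.numeric(mean_freq_hz), n),
    source = rep_len(as.character(source), n),
    label = rep_len(as.character(label), n),
    stringsAsFactors = FALSE
  )
  validate_events(df)
}

EVENT_SOURCES <- c("wavelet", "rms", "fusion", "expert", "truth")
EVENT_LABELS <- c("true", "false", "unknown")
SIGMA_BAND <- c(11, 16)

empty_events <- function() {
  spindle_events()
}

#' Validate and normalise an event set
#'
#' Checks the event-set invariants (positive duration, known source and label
#' vocabulary, amplitude positive when set, mean frequency inside the analysis
#' band when set), sorts events by onset within channel and drops exact
#' duplicates (identical channel and interval). Validation is idempotent.
#'
#' @param events a data frame with at least `channel`, `onset_s`, `offset_s`
#'   columns; missing optional columns are added.
#' @return the validated `event_set`.
#' @export
validate_events <- function(events) {
  stopifnot(is.data.frame(events))
  required <- c("channel", "onset_s", "offset_s")
  missing_cols <- setdiff(required, names(events))
  if (length(missing_cols) > 0) {
    stop("event set lacks required columns: ", paste(missing_cols, collapse = ", "))
  }
  defaults <- list(amplitude_pp_uV = NA_real_, mean_freq_hz = NA_real_,
                   source = "truth", label = "unknown")
  for (nm in names(defaults)) {
    if (!nm %in% names(events)) events[[nm]] <- defaults[[nm]]
  }
  events <- events[, c(required, names(defaults))]

  bad <- which(!(events$offset_s > events$onset_s) |
                 !is.finite(events$onset_s) | !is.finite(events$offset_s) |
                 (!is.na(events$amplitude_pp_uV) & events$amplitude_pp_uV <= 0) |
                 (!is.na(events$mean_freq_hz) &
                    (events$mean_freq_hz < SIGMA_BAND[1] |
                       events$mean_freq_hz > SIGMA_BAND[2])) |
                 !events$source %in% EVENT_SOURCES |
                 !events$label %in% EVENT_LABELS)
  if (length(bad) > 0) {
    stop("invalid spindle events at rows: ", paste(bad, collapse = ", "))
  }

  ord <- order(events$channel, events$onset_s, events$offset_s)
  events <- events[ord, , drop = FALSE]
  dup <- duplicated(events[, c("channel", "onset_s", "offset_s")])
  events <- events[!dup, , drop = FALSE]
  rownames(events) <- NULL
  class(events) <- c("event_set", "data.frame")
  events
}

#' Event durations in seconds
#'
#' @param events an `event_set` (or compatible data frame).
#' @return numeric vector `offset_s - onset_s`, strictly positive.
#' @export
event_duration <- function(events) {
  events$offset_s - events$onset_s
}

#' Do two events on the same channel overlap?
#'
#' Half-open interval semantics: `[0, 0.5)` and `[0.5, 1)` do not overlap.
#' Comparing events on different channels is a programming fault.
#'
#' @param a,b single-row event sets (or lists with `channel`, `onset_s`,
#'   `offset_s`).
#' @return logical scalar.
#' @export
events_overlap <- function(a, b) {
  if (!identical(as.character(a$channel), as.character(b$channel))) {
    stop("events_overlap called on events from different channels: ",
         a$channel, " vs ", b$channel)
  }
  a$onset_s < b$offset_s && b$onset_s < a$offset_s
}

#' Overlap fraction relative to the shorter event
#'
#' Length of the interval intersection divided by the shorter event's
#' duration; 1 for nested or identical events, 0 for disjoint ones.
#'
#' @inheritParams events_overlap
#' @return numeric scalar in `[0, 1]`.
#' @export
overlap_fraction <- function(a, b) {
  if (!identical(as.character(a$channel), as.character(b$channel))) {
    stop("overlap_fraction called on events from different channels: ",
         a$channel, " vs ", b$channel)
  }
  inter <- min(a$offset_s, b$offset_s) - max(a$onset_s, b$onset_s)
  if (inter <= 0) return(0)
  inter / min(a$offset_s - a$onset_s, b$offset_s - b$onset_s)
}

# Vectorised overlap fractions of one interval against columns of others;
# internal hot path for matching and partitioning (same channel assumed).
overlap_fraction_vec <- function(onset, offset, onsets, offsets) {
  inter <- pmin(offset, offsets) - pmax(onset, onsets)
  inter[inter < 0] <- 0
  inter / pmin(offset - onset, offsets - onsets)
}

#' Bind several event sets into one validated set
#'
#' @param ... event sets (or compatible data frames).
#' @return validated `event_set`.
#' @export
bind_events <- function(...) {
  parts <- Filter(function(x) !is.null(x) && nrow(x) > 0, list(...))
  if (length(parts) == 0) return(empty_events())
  validate_events(do.call(rbind, lapply(parts, as.data.frame)))
}

#' Construct a multichannel EEG recording
#'
#' @param subject_id subject identifier.
#' @param samples named list of equal-length numeric vectors, one per channel,
#'   in microvolts.
#' @param sampling_rate sampling rate in Hz (>= 100: the sigma band needs it).
#' @param start_offset_s seconds from recording start of sample 1.
#' @return an object of class `eeg_recording`.
#' @export
eeg_recording <- function(subject_id, samples, sampling_rate,
                          start_offset_s = 0) {
  stopifnot(is.list(samples), length(samples) >= 1)
  labels <- names(samples)
  if (is.null(labels) || any(!nzchar(labels))) {
    stop("samples must be a named list of channel vectors")
  }
  if (anyDuplicated(labels)) stop("channel labels must be unique")
  lens <- vapply(samples, length, integer(1))
  if (length(unique(lens)) != 1) stop("all channels must have the same length")
  if (!is.numeric(sampling_rate) || sampling_rate < 100) {
    stop("sampling_rate must be >= 100 Hz for sigma-band analysis")
  }
  structure(
    list(subject_id = as.character(subject_id),
         channel_labels = labels,
         sampling_rate = as.numeric(sampling_rate),
         samples = lapply(samples, as.numeric),
         start_offset_s = as.numeric(start_offset_s)),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  n <- length(x$samples[[1]])
  cat(sprintf("<eeg_recording> subject %s: %d channel(s) [%s], %.6g Hz, %.1f s\n",
              x$subject_id, length(x$samples),
              paste(x$channel_labels, collapse = ", "),
              x$sampling_rate, n / x$sampling_rate))
  invisible(x)
}

#' Recording duration in seconds
#' @param recording an [eeg_recording()].
#' @return duration in seconds.
#' @export
recording_duration <- function(recording) {
  length(recording$samples[[1]]) / recording$sampling_rate
}

# Seconds (relative to recording start) -> 1-based sample index; rounds half
# away from zero so detector outputs at different rates stay comparable.
time_to_index <- function(t_s, rate, start_offset_s = 0) {
  x <- (t_s - start_offset_s) * rate
  sign(x) * floor(abs(x) + 0.5) + 1
}

#' Construct a hypnogram
#'
#' @param stages character vector over `W`, `N1`, `N2`, `N3`, `REM`, one entry
#'   per scoring epoch.
#' @param epoch_length_s epoch length in seconds (30 by convention).
#' @return object of class `hypnogram`.
#' @export
hypnogram <- function(stages, epoch_length_s = 30) {
  stages <- as.character(stages)
  if (length(stages) == 0) stop("hypnogram must be non-empty")
  bad <- setdiff(unique(stages), c("W", "N1", "N2", "N3", "REM"))
  if (length(bad) > 0) stop("unknown sleep stage symbol(s): ", paste(bad, collapse = ", "))
  if (!is.numeric(epoch_length_s) || epoch_length_s <= 0) {
    stop("epoch_length_s must be positive")
  }
  structure(list(stages = stages, epoch_length_s = as.numeric(epoch_length_s)),
            class = "hypnogram")
}
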