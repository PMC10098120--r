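# Shared fixtures, built in code. Rendered subjects are memoised so several
# test files can reuse the same simulation without regenerating it.

.fixture_cache <- new.env(parent = emptyenv())

# Default 20-min synthetic subject (rendered EEG + truth + experts).
rendered_subject <- function(seed = 1, channels = "C3",
                             group = if (seed %% 2) "NS" else "DS") {
  key <- paste0("subj_", seed, "_", paste(channels, collapse = "-"), "_", group)
  if (is.null(.fixture_cache[[key]])) {
    params <- cohort_params(duration_min = 20, channels = channels)
    subj <- gen_subject(params, group, paste0("S", seed), seed = seed)
    subj$experts <- gen_experts(subj$truth, params$duration_min * 60, params,
                                seed = seed + 500)
    subj$params <- params
    .fixture_cache[[key]] <- subj
  }
  .fixture_cache[[key]]
}

# A tiny recording holding one pure tone, for feature closed-form tests.
tone_recording <- function(freq_hz = 13, peak_uV = 20, duration_s = 4,
                           rate = 256, channel = "C3") {
  tt <- seq(0, duration_s - 1 / rate, by = 1 / rate)
  samples <- stats::setNames(list(peak_uV * sin(2 * pi * freq_hz * tt)), channel)
  eeg_recording("tone", samples, rate)
}

# Quick event-set literal.
ev <- function(onset, offset, channel = "C3", source = "truth",
               label = "unknown") {
  spindle_events(channel = channel, onset_s = onset, offset_s = offset,
                 source = source, label = label)
}

recall_of <- function(pred, truth) {
  m <- match_events(pred, truth)
  m$tp / (m$tp + m$fn)
}

precision_of <- function(pred, truth) {
  if (nrow(pred) == 0) return(1)
  m <- match_events(pred, truth)
  m$tp / (m$tp + m$fp)
}
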