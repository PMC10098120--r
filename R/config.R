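#' Default run configuration
#'
#' All tunable parameters of the detection / fusion / evaluation pipeline with
#' their defaults. The sigma band (11-16 Hz) and the minimum duration (0.5 s)
#' follow the AASM spindle definition; the remaining numeric detector values
#' are this package's operating point and are all overridable from a YAML
#' file or per call.
#'
#' @return nested named list with components `band`, `duration`, `wavelet`,
#'   `rms`, `fusion`, `evaluation`.
#' @export
default_config <- function() {
  list(
    band = list(low_hz = 11, high_hz = 16),
    duration = list(min_s = 0.5, max_s = 3.0),
    wavelet = list(center_freq_hz = 13.5, n_cycles = 7, smooth_win_s = 0.1,
                   threshold_multiplier = 2.0),
    rms = list(window_s = 0.25, step_s = 0.1, percentile = 95,
               merge_gap_s = 0.2),
    fusion = list(k_min = 2, k_max = 6, reject_fraction = 0.5, seed = 1,
                  pool_subjects = FALSE),
    evaluation = list(match_fraction = 0.2, bin_s = 0.5)
  )
}

# Recursively overlay user values onto defaults, erroring on unknown keys so
# config typos never pass silently.
merge_config <- function(defaults, user, path = character()) {
  for (key in names(user)) {
    here <- paste(c(path, key), collapse = ".")
    if (!key %in% names(defaults)) stop("unknown config key: ", here)
    if (is.list(defaults[[key]])) {
      if (!is.list(user[[key]])) stop("config key ", here, " must be a mapping")
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], c(path, key))
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

validate_config <- function(config) {
  with(config, {
    if (band$low_hz >= band$high_hz) stop("band.low_hz must be < band.high_hz")
    if (duration$min_s >= duration$max_s) stop("duration.min_s must be < duration.max_s")
    positives <- c(band$low_hz, duration$min_s, wavelet$center_freq_hz,
                   wavelet$n_cycles, wavelet$smooth_win_s,
                   wavelet$threshold_multiplier, rms$window_s, rms$step_s,
                   rms$percentile, evaluation$match_fraction, evaluation$bin_s)
    if (any(!is.finite(positives)) || any(positives <= 0)) {
      stop("config thresholds and windows must be positive")
    }
    if (rms$percentile > 100) stop("rms.percentile must be in (0, 100]")
    if (fusion$k_min < 1 || fusion$k_max < fusion$k_min) {
      stop("fusion k range invalid")
    }
  })
  config
}

#' Load a run configuration from YAML
#'
#' Unspecified keys take the [default_config()] values; unknown keys are an
#' error.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return validated config list.
#' @export
load_config <- function(path = NULL) {
  config <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    if (!is.null(user)) config <- merge_config(config, user)
  }
  validate_config(config)
}
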