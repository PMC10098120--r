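# Synthetic annotated-PSG cohort generator: 1/f background EEG with embedded
# Hann-windowed sigma-band bursts, group-dependent spindle density, PSQI
# scores negatively coupled to density, and three imperfect simulated expert
# annotators. Serves as the fully-labelled stand-in for a private clinical
# cohort; every draw is deterministic under the master seed.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Default synthetic cohort parameters
#'
#' The generator's stated world: 20 sleep-disordered (DS) and 10 normal (NS)
#' subjects at 256 Hz on channels C3/C4/F3/F4; pink (1/f) background at
#' 15 uV RMS; per-group spindle density uniform over the published group
#' extremes (DS 0.89-2.83 /min, NS 1.68-3.5 /min); spindle frequency a
#' mixture with 70% mass in 12-14 Hz and the rest uniform over the remaining
#' sigma band; duration truncated-normal 0.9 +/- 0.25 s in [0.5, 1.5];
#' peak-to-peak amplitude uniform (DS 15-45 uV, NS 20-60 uV); PSQI =
#' round(clip(22 - 5.5 density + N(0, 1.2))) clipped to the group's score
#' range; experts detect with an amplitude-logistic probability calibrated to
#' 0.9 at the weakest amplitude (15 uV peak-to-peak) and saturating above it,
#' jitter boundaries with SD 0.05 s and add 0.2 false events per minute.
#'
#' @param duration_min per-subject recording length in minutes (20 for test
#'   runs; 480 emulates a full night).
#' @param channels channel labels to synthesise.
#' @param seed master seed.
#' @return parameter list.
#' @export
cohort_params <- function(duration_min = 20, channels = c("C3", "C4", "F3", "F4"),
                          seed = 42) {
  list(
    n_ds = 20, n_ns = 10,
    sampling_rate = 256,
    duration_min = duration_min,
    channels = channels,
    background_rms_uV = 15,
    spectral_alpha = 1,
    density_range = list(DS = c(0.89, 2.83), NS = c(1.68, 3.5)),
    freq_core = c(12, 14), freq_core_mass = 0.7,
    dur_mean_s = 0.9, dur_sd_s = 0.25, dur_range_s = c(0.5, 1.5),
    amp_range_uV = list(DS = c(15, 45), NS = c(20, 60)),
    psqi = list(a = 22, b = 5.5, noise_sd = 1.2,
                clip = list(DS = c(11, 21), NS = c(0, 10))),
    expert = list(p_mid_uV = 4, p_scale_uV = 5, jitter_sd_s = 0.05,
                  fp_per_min = 0.2),
    seed = seed
  )
}

#' Zero-coupling (null) variant of the cohort parameters
#'
#' Under the default coupling the PSQI score is clipped to the group's score
#' range, which deliberately ties scores to group membership. A type-I
#' calibration of the density-score correlation needs scores that are
#' independent of density but still vary, so the null world sets the density
#' coefficient to zero, centres the intercept mid-scale (10.5) and clips both
#' groups to the full 0-21 scale.
#'
#' @param params a [cohort_params()] list.
#' @return the parameters with the coupling nulled.
#' @export
null_coupling_params <- function(params) {
  params$psqi$b <- 0
  params$psqi$a <- 10.5
  params$psqi$clip <- list(DS = c(0, 21), NS = c(0, 21))
  params
}

#' Generate 1/f^alpha background EEG
#'
#' Gaussian noise spectrally shaped to a power-law spectrum and rescaled so
#' the overall RMS matches exactly.
#'
#' @param duration_s length in seconds.
#' @param rate sampling rate in Hz.
#' @param rms_uV target RMS in microvolts.
#' @param alpha spectral slope (1 = pink, 0 = white).
#' @param seed RNG seed.
#' @return numeric signal vector.
#' @export
gen_background <- function(duration_s, rate, rms_uV = 15, alpha = 1, seed = 1) {
  stopifnot(duration_s > 0, rate > 0, rms_uV > 0)
  n <- round(duration_s * rate)
  with_seed(seed, {
    spec <- stats::fft(stats::rnorm(n))
    freqs <- c(0, pmin(seq_len(n - 1), n - seq_len(n - 1))) * rate / n
    shape <- c(0, freqs[-1]^(-alpha / 2))
    x <- Re(stats::fft(spec * shape, inverse = TRUE)) / n
    x * rms_uV / sqrt(mean(x^2))
  })
}

#' Render one spindle burst
#'
#' `(A/2) Hann(t) sin(2 pi f t + phi)`: a waxing-and-waning sigma-band burst
#' whose maximum peak-to-peak amplitude equals `amplitude_pp_uV` to within a
#' few percent (the envelope peaks at 1 mid-burst).
#'
#' @param freq_hz oscillation frequency, inside `[11, 16]`.
#' @param amplitude_pp_uV target peak-to-peak amplitude in microvolts.
#' @param duration_s burst duration, inside `[0.5, 1.5]`.
#' @param rate sampling rate in Hz.
#' @param phase initial phase in radians.
#' @return numeric waveform of `round(duration_s * rate)` samples.
#' @export
gen_spindle <- function(freq_hz, amplitude_pp_uV, duration_s, rate,
                        phase = 0) {
  if (freq_hz < SIGMA_BAND[1] || freq_hz > SIGMA_BAND[2]) {
    stop("spindle frequency must lie in [11, 16] Hz")
  }
  if (duration_s < 0.5 || duration_s > 1.5) {
    stop("spindle duration must lie in [0.5, 1.5] s")
  }
  n <- round(duration_s * rate)
  tt <- seq(0, n - 1) / rate
  env <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
  (amplitude_pp_uV / 2) * env * sin(2 * pi * freq_hz * tt + phase)
}

rtruncnorm <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(n, mean, sd)
    out <- c(out, draw[draw >= lo & draw <= hi])
  }
  out[seq_len(n)]
}

draw_frequencies <- function(n, params) {
  core <- stats::runif(n) < params$freq_core_mass
  f <- numeric(n)
  f[core] <- stats::runif(sum(core), params$freq_core[1], params$freq_core[2])
  n_out <- sum(!core)
  if (n_out > 0) {
    # remaining mass uniform over [11,12) u (14,16], proportional to width
    lowside <- stats::runif(n_out) < 1 / 3
    f[!core][lowside] <- stats::runif(sum(lowside), SIGMA_BAND[1], params$freq_core[1])
    f[!core][!lowside] <- stats::runif(sum(!lowside), params$freq_core[2], SIGMA_BAND[2])
  }
  f
}

# Poisson-count events with uniformly drawn, non-overlapping onsets
# (colliding onsets redrawn).
place_events <- function(n_target, duration_s, durations) {
  onsets <- numeric(0); offsets <- numeric(0); kept <- integer(0)
  for (i in seq_len(n_target)) {
    for (try in seq_len(200)) {
      on <- stats::runif(1, 0, duration_s - durations[i])
      off <- on + durations[i]
      if (!any(on < offsets & onsets < off)) {
        onsets <- c(onsets, on); offsets <- c(offsets, off)
        kept <- c(kept, i)
        break
      }
    }
  }
  list(onsets = onsets, offsets = offsets, kept = kept)
}

cycle_hypnogram <- function(duration_min) {
  cycle <- c(rep("N1", 10), rep("N2", 90), rep("N3", 40), rep("REM", 30))
  hypnogram(rep(cycle, length.out = duration_min * 2), 30)
}

#' Generate one synthetic subject
#'
#' Draws the subject's spindle density (group-dependent), PSQI score (noisy
#' negative coupling to density), per-channel truth events (Poisson onsets,
#' non-overlap enforced per channel; independent draws across channels) and,
#' when `render = TRUE`, the EEG recording with the bursts embedded in pink
#' noise.
#'
#' @param params [cohort_params()] list.
#' @param group `"DS"` or `"NS"`.
#' @param subject_id subject identifier.
#' @param seed per-subject seed.
#' @param render render EEG samples (FALSE gives the cheap events-only path
#'   used by the statistical calibration tests).
#' @return list with `recording` (or `NULL`), `truth` (labelled
#'   `event_set`), `hypnogram`, `subject` (1-row data frame with `psqi`,
#'   `true_density_per_min`).
#' @export
gen_subject <- function(params, group = "DS", subject_id = "S1", seed = 1,
                        render = TRUE) {
  duration_s <- params$duration_min * 60
  with_seed(seed, {
    dr <- params$density_range[[group]]
    density <- stats::runif(1, dr[1], dr[2])
    psqi_raw <- params$psqi$a - params$psqi$b * density +
      stats::rnorm(1, 0, params$psqi$noise_sd)
    clip <- params$psqi$clip[[group]]
    psqi <- round(min(clip[2], max(clip[1], psqi_raw)))

    truth_rows <- list()
    signals <- list()
    ar <- params$amp_range_uV[[group]]
    for (ch in params$channels) {
      n_ev <- stats::rpois(1, density * params$duration_min)
      if (n_ev > 0) {
        durs <- rtruncnorm(n_ev, params$dur_mean_s, params$dur_sd_s,
                           params$dur_range_s[1], params$dur_range_s[2])
        freqs <- draw_frequencies(n_ev, params)
        amps <- stats::runif(n_ev, ar[1], ar[2])
        phases <- stats::runif(n_ev, 0, 2 * pi)
        placed <- place_events(n_ev, duration_s, durs)
        truth_rows[[ch]] <- data.frame(
          channel = ch, onset_s = placed$onsets, offset_s = placed$offsets,
          amplitude_pp_uV = amps[placed$kept],
          mean_freq_hz = freqs[placed$kept],
          source = "truth", label = "true", stringsAsFactors = FALSE)
      } else {
        truth_rows[[ch]] <- NULL
      }
      if (render) {
        x <- gen_background(duration_s, params$sampling_rate,
                            params$background_rms_uV, params$spectral_alpha,
                            seed = stats::runif(1, 1, 2^30))
        if (n_ev > 0) {
          tr <- truth_rows[[ch]]
          for (i in seq_len(nrow(tr))) {
            burst <- gen_spindle(tr$mean_freq_hz[i], tr$amplitude_pp_uV[i],
                                 tr$offset_s[i] - tr$onset_s[i],
                                 params$sampling_rate,
                                 phase = phases[placed$kept][i])
            i0 <- time_to_index(tr$onset_s[i], params$sampling_rate)
            idx <- i0:(i0 + length(burst) - 1)
            ok <- idx >= 1 & idx <= length(x)
            x[idx[ok]] <- x[idx[ok]] + burst[ok]
          }
        }
        signals[[ch]] <- x
      }
    }
    truth <- if (length(truth_rows) == 0) empty_events() else
      validate_events(do.call(rbind, Filter(Negate(is.null), truth_rows)))
    attr(truth, "complete") <- TRUE   # ledger knows every true spindle
    recording <- if (render) {
      eeg_recording(subject_id, signals, params$sampling_rate)
    } else NULL
    list(
      recording = recording,
      truth = truth,
      hypnogram = cycle_hypnogram(params$duration_min),
      subject = data.frame(subject_id = subject_id, group = group,
                           psqi = psqi,
                           true_density_per_min = nrow(truth) /
                             (length(params$channels) * params$duration_min),
                           stringsAsFactors = FALSE)
    )
  })
}

#' Simulate three imperfect expert annotators
#'
#' Each expert keeps each truth event with an amplitude-logistic detection
#' probability (at least 0.9 across the generated amplitude range), jitters both
#' boundaries with Gaussian noise (duration floored at 0.5 s), and adds
#' Poisson false events labelled `"false"` in the returned sets.
#'
#' @param truth labelled truth `event_set` (with amplitudes).
#' @param duration_s recording length in seconds (for false-event placement).
#' @param params [cohort_params()] list (`$expert` component is used).
#' @param seed RNG seed.
#' @return list of 3 `event_set`s with `source = "expert"`.
#' @export
gen_experts <- function(truth, duration_s, params = cohort_params(), seed = 1) {
  ep <- params$expert
  with_seed(seed, {
    lapply(1:3, function(e) {
      rows <- list()
      if (nrow(truth) > 0) {
        amp <- truth$amplitude_pp_uV
        amp[is.na(amp)] <- mean(params$amp_range_uV$DS)
        keep <- stats::runif(nrow(truth)) <
          stats::plogis((amp - ep$p_mid_uV) / ep$p_scale_uV)
        if (any(keep)) {
          kept <- truth[keep, , drop = FALSE]
          on <- kept$onset_s + stats::rnorm(nrow(kept), 0, ep$jitter_sd_s)
          off <- kept$offset_s + stats::rnorm(nrow(kept), 0, ep$jitter_sd_s)
          on <- pmax(0, on)
          off <- pmax(off, on + 0.5)                   # duration floor
          off <- pmin(off, duration_s)
          rows[[1]] <- data.frame(channel = kept$channel, onset_s = on,
                                  offset_s = off, source = "expert",
                                  label = "true", stringsAsFactors = FALSE)
        }
      }
      channels <- unique(truth$channel)
      if (length(channels) == 0) channels <- "C3"
      n_fp <- stats::rpois(1, ep$fp_per_min * duration_s / 60 * length(channels))
      if (n_fp > 0) {
        durs <- rtruncnorm(n_fp, params$dur_mean_s, params$dur_sd_s,
                           params$dur_range_s[1], params$dur_range_s[2])
        on <- stats::runif(n_fp, 0, duration_s - durs)
        rows[[2]] <- data.frame(channel = sample(channels, n_fp, replace = TRUE),
                                onset_s = on, offset_s = on + durs,
                                source = "expert", label = "false",
                                stringsAsFactors = FALSE)
      }
      if (length(rows) == 0) return(empty_events())
      validate_events(do.call(rbind, rows))
    })
  })
}

#' Generate a full synthetic cohort
#'
#' `n_ds + n_ns` subjects, each with truth events, hypnogram, PSQI score,
#' three expert annotations and (optionally) rendered EEG. When `dir` is
#' given, the cohort is also written to disk: per-subject EDF,
#' `<id>_truth_events.csv`, `<id>_expert{1,2,3}_events.csv`,
#' `<id>_hypnogram.csv`, plus `subjects.csv` and `params.yaml`.
#'
#' @param params [cohort_params()] list.
#' @param dir optional output directory.
#' @param render render EEG samples.
#' @return list with `subjects` (data frame) and `cohort` (per-subject
#'   lists: `recording`, `truth`, `experts`, `hypnogram`).
#' @export
gen_cohort <- function(params = cohort_params(), dir = NULL, render = TRUE) {
  ids <- c(paste0("DS", seq_len(params$n_ds)), paste0("NS", seq_len(params$n_ns)))
  groups <- rep(c("DS", "NS"), c(params$n_ds, params$n_ns))
  duration_s <- params$duration_min * 60
  if (!is.null(dir) && !dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", dir)
  }
  cohort <- vector("list", length(ids))
  names(cohort) <- ids
  subj_rows <- list()
  for (i in seq_along(ids)) {
    subj <- gen_subject(params, groups[i], ids[i],
                        seed = params$seed + 1000 * i, render = render)
    subj$experts <- gen_experts(subj$truth, duration_s, params,
                                seed = params$seed + 1000 * i + 500)
    cohort[[i]] <- subj
    subj_rows[[i]] <- subj$subject
    if (!is.null(dir)) {
      base <- file.path(dir, ids[i])
      if (render) write_edf(subj$recording, paste0(base, ".edf"))
      write_events(subj$truth, paste0(base, "_truth_events.csv"), ids[i])
      for (e in 1:3) {
        write_events(subj$experts[[e]],
                     paste0(base, "_expert", e, "_events.csv"), ids[i])
      }
      write_hypnogram(subj$hypnogram, paste0(base, "_hypnogram.csv"))
    }
  }
  subjects <- do.call(rbind, subj_rows)
  if (!is.null(dir)) {
    utils::write.csv(subjects, file.path(dir, "subjects.csv"),
                     row.names = FALSE, quote = FALSE)
    yaml::write_yaml(params, file.path(dir, "params.yaml"))
  }
  list(subjects = subjects, cohort = cohort)
}
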