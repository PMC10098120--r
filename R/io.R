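# Readers/writers: EDF recordings (minimal EDF dialect: 16-bit samples,
# 1-second data records), CSV event annotations (onset + duration), CSV
# hypnograms, the subjects table, and the packaged PSQI / first-cycle
# fixture.

pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width, flag = " ")
}

#' Write a recording to EDF
#'
#' Minimal EDF writer: one-second data records, 16-bit samples, per-channel
#' physical scaling chosen symmetric around zero, physical dimension uV.
#' Requires an integer sampling rate and a whole number of seconds of data.
#'
#' @param recording an [eeg_recording()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path) {
  if (length(recording$samples) == 0) stop("recording has no channels")
  n <- length(recording$samples[[1]])
  if (n == 0) stop("recording has zero-length samples")
  rate <- recording$sampling_rate
  if (rate != round(rate)) stop("EDF writer requires an integer sampling rate")
  if (n %% rate != 0) stop("EDF writer requires a whole number of seconds")
  n_rec <- n / rate
  ns <- length(recording$samples)

  phys_max <- vapply(recording$samples,
                     function(x) max(abs(x), 1e-6), numeric(1))
  dig_max <- 32767; dig_min <- -32768

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8),
    pad_field(recording$subject_id, 80),
    pad_field("spindlefusion synthetic", 80),
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    pad_field(256 * (1 + ns), 8),
    pad_field("", 44),
    pad_field(n_rec, 8),
    pad_field(1, 8),
    pad_field(ns, 4)
  )
  fields <- c(
    vapply(recording$channel_labels, pad_field, "", width = 16),
    rep(pad_field("", 80), ns),
    rep(pad_field("uV", 8), ns),
    vapply(-phys_max, function(v) pad_field(formatC(v, format = "g", digits = 7), 8), ""),
    vapply(phys_max, function(v) pad_field(formatC(v, format = "g", digits = 7), 8), ""),
    rep(pad_field(dig_min, 8), ns),
    rep(pad_field(dig_max, 8), ns),
    rep(pad_field("", 80), ns),
    rep(pad_field(rate, 8), ns),
    rep(pad_field("", 32), ns)
  )
  writeChar(paste0(hdr, paste(fields, collapse = "")), con, eos = NULL)

  # re-read the physical extrema exactly as a reader will parse them, so the
  # digital encoding inverts bit-exactly
  pm <- as.numeric(formatC(phys_max, format = "g", digits = 7))
  scale <- (2 * pm) / (dig_max - dig_min)
  digital <- mapply(function(x, p, s) {
    d <- round((x - (-p)) / s) + dig_min
    as.integer(pmax(dig_min, pmin(dig_max, d)))
  }, recording$samples, pm, scale, SIMPLIFY = FALSE)

  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * rate + 1):(r * rate)
    for (ch in seq_len(ns)) {
      writeBin(digital[[ch]][idx], con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read a recording from EDF
#'
#' @param path EDF/EDF+ file.
#' @param wanted_channels channel labels to load; all wanted channels must be
#'   present and share one sampling rate (no implicit resampling). `NULL`
#'   loads every channel.
#' @param subject_id subject id to stamp; default: the EDF patient field.
#' @return an [eeg_recording()] with samples in microvolts.
#' @export
read_edf <- function(path, wanted_channels = NULL, subject_id = NULL) {
  if (!file.exists(path)) stop("EDF file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nchars) trimws(readChar(con, nchars, useBytes = TRUE))
  version <- rd(8)
  patient <- rd(80)
  rd(80); rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  sig_field <- function(width, type = c("char", "num")) {
    vals <- vapply(seq_len(ns), function(i) rd(width), "")
    if (match.arg(type) == "num") as.numeric(vals) else vals
  }
  labels <- sig_field(16)
  sig_field(80)
  phys_dim <- sig_field(8)
  phys_min <- sig_field(8, "num")
  phys_max <- sig_field(8, "num")
  dig_min <- sig_field(8, "num")
  dig_max <- sig_field(8, "num")
  sig_field(80)
  spr <- as.integer(sig_field(8))
  sig_field(32)

  if (is.null(wanted_channels)) wanted_channels <- labels
  missing_ch <- setdiff(wanted_channels, labels)
  if (length(missing_ch) > 0) {
    stop("channel(s) not in EDF file: ", paste(missing_ch, collapse = ", "))
  }
  sel <- match(wanted_channels, labels)
  rates <- spr[sel] / rec_dur
  if (length(unique(rates)) != 1) {
    stop("wanted channels have mixed sampling rates: ",
         paste(unique(rates), collapse = ", "))
  }
  dim_ok <- tolower(phys_dim[sel]) %in% c("uv", "µv", "mv")
  if (!all(dim_ok)) {
    stop("unsupported physical dimension(s): ",
         paste(unique(phys_dim[sel][!dim_ok]), collapse = ", "),
         " (need uV or mV)")
  }
  to_uV <- ifelse(tolower(phys_dim[sel]) == "mv", 1000, 1)

  rec_len <- sum(spr)
  samples <- stats::setNames(
    lapply(sel, function(i) numeric(spr[i] * n_rec)), wanted_channels)
  offsets <- cumsum(c(0, spr))[-(ns + 1)]
  for (r in seq_len(n_rec)) {
    rec <- readBin(con, integer(), n = rec_len, size = 2, endian = "little")
    for (j in seq_along(sel)) {
      i <- sel[j]
      dig <- rec[(offsets[i] + 1):(offsets[i] + spr[i])]
      phys <- phys_min[i] +
        (dig - dig_min[i]) * (phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i])
      samples[[j]][((r - 1) * spr[i] + 1):(r * spr[i])] <- phys * to_uV[j]
    }
  }
  eeg_recording(subject_id = if (is.null(subject_id)) patient else subject_id,
                samples = samples, sampling_rate = rates[1])
}

#' Read spindle events from CSV
#'
#' Expected header: `subject_id,channel,onset_s,duration_s,source,label`
#' (label `"1"` = true, `"0"` = false, empty = unknown). Offsets are
#' reconstructed as onset + duration.
#'
#' @param path CSV file.
#' @return validated `event_set`.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("events file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("subject_id", "channel", "onset_s", "duration_s", "source", "label")
  if (!all(need %in% names(df))) {
    stop("events CSV lacks columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  if (nrow(df) == 0) return(empty_events())
  onset <- suppressWarnings(as.numeric(df$onset_s))
  dur <- suppressWarnings(as.numeric(df$duration_s))
  bad <- which(is.na(onset) | is.na(dur) | dur <= 0)
  if (length(bad) > 0) {
    stop("malformed event row(s) at line(s): ",
         paste(bad + 1, collapse = ", "))  # +1 for the header line
  }
  label <- ifelse(df$label == "1", "true",
                  ifelse(df$label == "0", "false", "unknown"))
  out <- spindle_events(channel = df$channel, onset_s = onset,
                        offset_s = onset + dur, source = df$source,
                        label = label)
  attr(out, "subject_id") <- df$subject_id[1]
  out
}

#' Write spindle events to CSV
#'
#' @param events an `event_set`.
#' @param path output file.
#' @param subject_id subject id column value.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path, subject_id = "unknown") {
  if (!is.null(attr(events, "subject_id"))) subject_id <- attr(events, "subject_id")
  label <- c(true = "1", false = "0", unknown = "")[events$label]
  df <- data.frame(subject_id = rep(subject_id, nrow(events)),
                   channel = events$channel,
                   onset_s = events$onset_s,
                   duration_s = events$offset_s - events$onset_s,
                   source = events$source,
                   label = unname(label),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a hypnogram from CSV
#'
#' Expected columns: `epoch_index,stage` (stages W/N1/N2/N3/REM, 30 s epochs
#' unless overridden).
#'
#' @param path CSV file.
#' @param epoch_length_s epoch length in seconds.
#' @return a [hypnogram()].
#' @export
read_hypnogram <- function(path, epoch_length_s = 30) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("epoch_index", "stage") %in% names(df))) {
    stop("hypnogram CSV needs columns epoch_index,stage")
  }
  df <- df[order(df$epoch_index), ]
  hypnogram(df$stage, epoch_length_s)
}

#' Write a hypnogram to CSV
#' @param hyp a [hypnogram()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_hypnogram <- function(hyp, path) {
  utils::write.csv(data.frame(epoch_index = seq_along(hyp$stages) - 1,
                              stage = hyp$stages),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read the subjects table
#'
#' Columns: `subject_id,group,psqi[,first_cycle_min,first_cycle_spindles]`.
#' Group must be `DS` (sleep-disordered) or `NS` (normal); PSQI must lie in
#' 0-21. A DS subject with PSQI < 11 (the conventional sleep-disorder cut)
#' triggers a warning, not an error.
#'
#' @param path CSV file.
#' @return data frame of subject records.
#' @export
read_subjects <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "psqi")
  if (!all(need %in% names(df))) {
    stop("subjects CSV lacks columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  if (!all(df$group %in% c("DS", "NS"))) {
    stop("unknown group label(s): ",
         paste(setdiff(unique(df$group), c("DS", "NS")), collapse = ", "))
  }
  if (any(df$psqi < 0 | df$psqi > 21 | df$psqi != round(df$psqi))) {
    stop("psqi scores must be integers in [0, 21]")
  }
  inconsistent <- (df$group == "DS" & df$psqi < 11) |
    (df$group == "NS" & df$psqi >= 11)
  if (any(inconsistent)) {
    warning("group label inconsistent with the PSQI >= 11 cut for: ",
            paste(df$subject_id[inconsistent], collapse = ", "))
  }
  df
}

#' The packaged PSQI / first-cycle subjects fixture
#'
#' The published 30-subject table (20 sleep-disordered, 10 normal controls)
#' with each subject's PSQI score, first-cycle duration in minutes and
#' first-cycle spindle count, shipped as a plain CSV.
#'
#' @return data frame of 30 subject records.
#' @export
subjects_fixture <- function() {
  read_subjects(system.file("extdata", "psqi_first_cycle_subjects.csv",
                            package = "spindlefusion", mustWork = TRUE))
}
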