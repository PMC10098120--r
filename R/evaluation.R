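# Evaluation against multi-expert consensus: truth construction (two-of-three
# agreement), greedy one-to-one event matching, bin-level confusion for the
# negative-dependent metrics, the five derived metrics, per-subject variance
# tables, and the three-way detector comparison.

#' Consensus ground truth from three expert annotations
#'
#' Two expert events match when they overlap by at least `match_fraction` of
#' the shorter event. Any event group supported by at least two of the three
#' experts becomes one true event whose interval is the union of the matched
#' intervals (deduplicated across the three pairings); expert events
#' supported by no other expert form the non-spindle (false) set.
#'
#' @param expert_sets list of exactly 3 `event_set`s.
#' @param match_fraction minimum overlap fraction (default 0.2).
#' @return list with `true_set` and `false_set` (class `consensus_truth`).
#' @export
consensus <- function(expert_sets, match_fraction = 0.2) {
  if (length(expert_sets) != 3) stop("consensus requires exactly 3 expert sets")
  sets <- lapply(expert_sets, validate_events)
  supported <- lapply(sets, function(s) rep(FALSE, nrow(s)))
  candidates <- list()
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    m <- greedy_match(sets[[pair[1]]], sets[[pair[2]]], match_fraction)
    if (nrow(m$pairs) > 0) {
      supported[[pair[1]]][m$pairs$i] <- TRUE
      supported[[pair[2]]][m$pairs$j] <- TRUE
      a <- sets[[pair[1]]][m$pairs$i, , drop = FALSE]
      b <- sets[[pair[2]]][m$pairs$j, , drop = FALSE]
      candidates[[length(candidates) + 1]] <- data.frame(
        channel = a$channel,
        onset_s = pmin(a$onset_s, b$onset_s),
        offset_s = pmax(a$offset_s, b$offset_s),
        stringsAsFactors = FALSE)
    }
  }
  true_set <- if (length(candidates) == 0) empty_events() else {
    cand <- do.call(rbind, candidates)
    merged <- merge_overlapping(cand)
    spindle_events(merged$channel, merged$onset_s, merged$offset_s,
                   source = "truth", label = "true")
  }
  false_rows <- mapply(function(s, sup) s[!sup, , drop = FALSE],
                       sets, supported, SIMPLIFY = FALSE)
  false_set <- do.call(bind_events, false_rows)
  if (nrow(false_set) > 0) {
    false_set$source <- "truth"; false_set$label <- "false"
    false_set <- validate_events(false_set)
  }
  structure(list(true_set = true_set, false_set = false_set),
            class = "consensus_truth")
}

# union-merge any overlapping intervals per channel
merge_overlapping <- function(df) {
  out <- list()
  for (ch in unique(df$channel)) {
    d <- df[df$channel == ch, , drop = FALSE]
    d <- d[order(d$onset_s, d$offset_s), , drop = FALSE]
    on <- d$onset_s[1]; off <- d$offset_s[1]
    for (i in seq_len(nrow(d))[-1]) {
      if (d$onset_s[i] < off) {
        off <- max(off, d$offset_s[i])
      } else {
        out[[length(out) + 1]] <- data.frame(channel = ch, onset_s = on,
                                             offset_s = off)
        on <- d$onset_s[i]; off <- d$offset_s[i]
      }
    }
    out[[length(out) + 1]] <- data.frame(channel = ch, onset_s = on,
                                         offset_s = off)
  }
  do.call(rbind, out)
}

#' Flatten a consensus truth into one labelled reference set
#'
#' @param truth a `consensus_truth`.
#' @return labelled `event_set` usable as [fuse_detections()] reference.
#' @export
consensus_reference <- function(truth) {
  bind_events(truth$true_set, truth$false_set)
}

# Greedy one-to-one matching in onset order; returns indices of matched pairs.
greedy_match <- function(pred, truth, match_fraction = 0.2) {
  pairs <- data.frame(i = integer(), j = integer())
  if (nrow(pred) > 0 && nrow(truth) > 0) {
    truth_used <- rep(FALSE, nrow(truth))
    for (i in seq_len(nrow(pred))) {
      cand <- which(!truth_used & truth$channel == pred$channel[i])
      if (length(cand) == 0) next
      fr <- overlap_fraction_vec(pred$onset_s[i], pred$offset_s[i],
                                 truth$onset_s[cand], truth$offset_s[cand])
      ok <- cand[fr >= match_fraction]
      if (length(ok) > 0) {
        j <- ok[which.max(fr[match(ok, cand)])]
        truth_used[j] <- TRUE
        pairs <- rbind(pairs, data.frame(i = i, j = j))
      }
    }
  }
  list(pairs = pairs)
}

#' Event-level matching counts
#'
#' Greedy one-to-one matching in onset order: a prediction matches an
#' unmatched truth event when their overlap is at least `match_fraction` of
#' the shorter event. `tp + fn = |truth|` and `tp + fp = |pred|` always hold.
#'
#' @param pred,truth_true validated `event_set`s.
#' @param match_fraction minimum overlap fraction (default 0.2).
#' @return list with `tp`, `fp`, `fn`.
#' @export
match_events <- function(pred, truth_true, match_fraction = 0.2) {
  m <- greedy_match(pred, truth_true, match_fraction)
  tp <- nrow(m$pairs)
  list(tp = tp, fp = nrow(pred) - tp, fn = nrow(truth_true) - tp)
}

#' Bin-level confusion counts
#'
#' The scoring window is discretised into bins of `bin_s`; a bin counts as
#' positive for a set when at least 50% of the bin is covered by any of its
#' events. True negatives -- undefined at event level -- are the bins
#' negative in both sets.
#'
#' @param pred,truth_true `event_set`s (single channel or pooled).
#' @param window a `scoring_window`.
#' @param bin_s bin width in seconds (default 0.5).
#' @return list with `tp`, `fp`, `fn`, `tn`.
#' @export
binwise_confusion <- function(pred, truth_true, window, bin_s = 0.5) {
  for (s in list(pred, truth_true)) {
    if (nrow(s) > 0 && (min(s$onset_s) < window$start_s ||
                        max(s$offset_s) > window$end_s)) {
      stop("event outside the scoring window")
    }
  }
  n_bins <- floor((window$end_s - window$start_s) / bin_s)
  edges <- window$start_s + bin_s * seq(0, n_bins)
  coverage <- function(set) {
    cov <- numeric(n_bins)
    for (i in seq_len(nrow(set))) {
      lo <- pmax(edges[-length(edges)], set$onset_s[i])
      hi <- pmin(edges[-1], set$offset_s[i])
      cov <- cov + pmax(0, hi - lo)
    }
    cov >= bin_s / 2
  }
  p <- coverage(pred); t <- coverage(truth_true)
  list(tp = sum(p & t), fp = sum(p & !t), fn = sum(!p & t), tn = sum(!p & !t))
}

#' The five evaluation metrics, as percentages
#'
#' recall = tp/(tp+fn); precision = tp/(tp+fp); specificity = tn/(tn+fp);
#' accuracy = (tp+tn)/total; F1 = 2PR/(P+R). A metric whose denominator is
#' zero is reported as 0 and listed in the `flagged` attribute.
#'
#' @param counts list with `tp`, `fp`, `fn` and optionally `tn` (0 when
#'   absent; specificity/accuracy are then meaningless and flagged).
#' @return named numeric vector of percentages with attribute `flagged`.
#' @export
metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  tn <- if (is.null(counts$tn)) 0 else counts$tn
  if (tp + fp + fn + tn == 0) stop("all confusion counts are zero")
  flagged <- character()
  safe <- function(num, den, name) {
    if (den == 0) { flagged <<- c(flagged, name); return(0) }
    100 * num / den
  }
  recall <- safe(tp, tp + fn, "recall")
  precision <- safe(tp, tp + fp, "precision")
  specificity <- safe(tn, tn + fp, "specificity")
  accuracy <- safe(tp + tn, tp + fp + fn + tn, "accuracy")
  f1 <- if (precision + recall == 0) {
    flagged <- c(flagged, "f1"); 0
  } else 2 * precision * recall / (precision + recall)
  structure(c(recall = recall, precision = precision,
              specificity = specificity, accuracy = accuracy, f1 = f1),
            flagged = flagged)
}

#' Per-metric sample variance across subjects
#'
#' @param per_subject data frame with a `subject_id` column and one column
#'   per metric, on the percentage scale.
#' @return named numeric vector of sample (n-1) variances.
#' @export
variance_table <- function(per_subject) {
  metric_cols <- setdiff(names(per_subject),
                         c("subject_id", "method", "channel"))
  if (nrow(per_subject) < 2) stop("variance requires >= 2 subjects")
  vapply(per_subject[metric_cols], stats::var, numeric(1))
}

# Evaluate one prediction set against a truth set: event-level recall /
# precision / F1, bin-level specificity / accuracy.
evaluate_events <- function(pred, truth_true, window, match_fraction = 0.2,
                            bin_s = 0.5) {
  ev <- match_events(pred, truth_true, match_fraction)
  bin <- binwise_confusion(pred, truth_true, window, bin_s)
  m_ev <- metrics(ev)
  m_bin <- metrics(bin)
  c(recall = m_ev[["recall"]], precision = m_ev[["precision"]],
    specificity = m_bin[["specificity"]], accuracy = m_bin[["accuracy"]],
    f1 = m_ev[["f1"]])
}

#' Compare wavelet, RMS and fusion detectors on a cohort
#'
#' Runs the three detectors on every subject and channel, evaluates each
#' against the subject's truth, and summarises max / min / mean and the
#' across-subject variance of every metric per method.
#'
#' @param cohort list of subjects, each a list with `recording`, `truth`
#'   (labelled `event_set`; its `label == "true"` rows are the positives),
#'   `hypnogram`.
#' @param config run configuration.
#' @param channels channels to evaluate (default: all in each recording).
#' @return list with `per_subject` (long data frame) and `summary`
#'   (method x metric max/min/mean/variance).
#' @export
compare_detectors <- function(cohort, config = default_config(),
                              channels = NULL) {
  if (length(cohort) == 0) stop("empty cohort")
  params <- detector_params(config)
  rows <- list()
  for (subj in cohort) {
    rec <- subj$recording
    win <- scoring_window(subj$hypnogram, recording_duration(rec))
    chans <- if (is.null(channels)) rec$channel_labels else channels
    dets <- list(wavelet = empty_events(), rms = empty_events())
    for (ch in chans) {
      x <- rec$samples[[ch]]
      dets$wavelet <- bind_events(dets$wavelet,
        detect_wavelet(x, rec$sampling_rate, params, ch, win))
      dets$rms <- bind_events(dets$rms,
        detect_rms(x, rec$sampling_rate, params, ch, win))
    }
    dets$fusion <- fuse_detections(rec, dets$wavelet, dets$rms,
                                   reference = subj$truth, config = config)
    truth_true <- subj$truth[subj$truth$label == "true" &
                               subj$truth$channel %in% chans, , drop = FALSE]
    for (method in names(dets)) {
      m <- evaluate_events(dets[[method]], truth_true, win,
                           config$evaluation$match_fraction,
                           config$evaluation$bin_s)
      rows[[length(rows) + 1]] <- cbind(
        data.frame(method = method, subject_id = rec$subject_id,
                   stringsAsFactors = FALSE),
        as.data.frame(t(m)))
    }
  }
  per_subject <- do.call(rbind, rows)
  metric_cols <- c("recall", "precision", "specificity", "accuracy", "f1")
  summary_rows <- lapply(split(per_subject, per_subject$method), function(d) {
    stats_df <- data.frame(method = d$method[1], stringsAsFactors = FALSE)
    for (mc in metric_cols) {
      stats_df[[paste0(mc, "_max")]] <- max(d[[mc]])
      stats_df[[paste0(mc, "_min")]] <- min(d[[mc]])
      stats_df[[paste0(mc, "_mean")]] <- mean(d[[mc]])
      stats_df[[paste0(mc, "_var")]] <- if (nrow(d) >= 2) stats::var(d[[mc]]) else NA_real_
    }
    stats_df
  })
  if (length(unique(per_subject$subject_id)) < 2) {
    warning("single-subject cohort: variance columns are NA")
  }
  list(per_subject = per_subject, summary = do.call(rbind, summary_rows))
}
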