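# Detector fusion: detections made by both detectors ("overlapping spindles")
# are trusted and reduced to one representative per overlap chain (longest
# event wins); detector-unique detections are clustered on (amplitude, mean
# frequency) and clusters dominated by labelled non-spindles are discarded.

#' Partition two detectors' event sets into overlap and unique sets
#'
#' Per channel, maximal groups of mutually/transitively overlapping events
#' drawn from both detectors are found. Groups containing events from both
#' detectors contribute one representative (see [resolve_overlap()]) to the
#' overlap set; events overlapping nothing from the other detector go to the
#' unique set.
#'
#' @param setA,setB validated `event_set`s (conventionally wavelet and RMS).
#' @return list with `overlap` and `unique` event sets.
#' @export
partition_detections <- function(setA, setB) {
  a <- as.data.frame(setA); b <- as.data.frame(setB)
  a$det <- rep("A", nrow(a)); b$det <- rep("B", nrow(b))
  all_ev <- rbind(a, b)
  if (nrow(all_ev) == 0) {
    return(list(overlap = empty_events(), unique = empty_events()))
  }
  overlap_rows <- list(); unique_rows <- list()
  for (ch in unique(all_ev$channel)) {
    ev <- all_ev[all_ev$channel == ch, , drop = FALSE]
    ev <- ev[order(ev$onset_s, ev$offset_s), , drop = FALSE]
    # sweep: a new component starts when the next onset clears every open interval
    comp <- integer(nrow(ev)); cid <- 0L; max_off <- -Inf
    for (i in seq_len(nrow(ev))) {
      if (ev$onset_s[i] >= max_off) cid <- cid + 1L
      comp[i] <- cid
      max_off <- max(max_off, ev$offset_s[i])
    }
    for (g in split(ev, comp)) {
      if (length(unique(g$det)) == 2) {
        overlap_rows[[length(overlap_rows) + 1]] <- resolve_overlap(g)
      } else {
        unique_rows[[length(unique_rows) + 1]] <- g
      }
    }
  }
  strip <- function(rows) {
    if (length(rows) == 0) return(empty_events())
    df <- do.call(rbind, rows)
    validate_events(df[, setdiff(names(df), "det"), drop = FALSE])
  }
  list(overlap = strip(overlap_rows), unique = strip(unique_rows))
}

#' Pick the representative of an overlap group
#'
#' The event with the longest duration; ties broken by earlier onset, then by
#' detector order (wavelet before RMS).
#'
#' @param group data frame of >= 2 chained overlapping events.
#' @return single-row data frame.
#' @export
resolve_overlap <- function(group) {
  if (nrow(group) < 2) stop("resolve_overlap needs a group of >= 2 events")
  det_rank <- if ("det" %in% names(group)) match(group$det, c("A", "B"))
              else match(group$source, c("wavelet", "rms"))
  ord <- order(-(group$offset_s - group$onset_s), group$onset_s, det_rank)
  group[ord[1], , drop = FALSE]
}

# z-score columns with sample SD (n-1); zero-SD (or single-row) columns map
# to 0 so degenerate populations stay clusterable.
standardize_features <- function(m) {
  if (nrow(m) == 0) return(m)
  mu <- colMeans(m)
  sdv <- apply(m, 2, stats::sd)
  out <- sweep(m, 2, mu)
  for (j in seq_len(ncol(m))) {
    out[, j] <- if (is.na(sdv[j]) || sdv[j] == 0) 0 else out[, j] / sdv[j]
  }
  out
}

# deterministic k-means++ seeding
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums((x - matrix(x[centers[1], ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1)) {
    probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j + 1] <- sample.int(n, 1, prob = probs)
    d2_new <- rowSums((x - matrix(x[centers[j + 1], ], n, ncol(x), byrow = TRUE))^2)
    d2 <- pmin(d2, d2_new)
  }
  x[centers, , drop = FALSE]
}

lloyd <- function(x, centers, tol = 1e-6, max_iter = 300) {
  k <- nrow(centers)
  n <- nrow(x)
  assignment <- integer(n)
  for (iter in seq_len(max_iter)) {
    d <- vapply(seq_len(k), function(j) {
      rowSums((x - matrix(centers[j, ], n, ncol(x), byrow = TRUE))^2)
    }, numeric(n))
    d <- matrix(d, nrow = n)
    assignment <- max.col(-d, ties.method = "first")
    new_centers <- centers
    for (j in seq_len(k)) {
      members <- assignment == j
      if (any(members)) {
        new_centers[j, ] <- colMeans(x[members, , drop = FALSE])
      } else {
        new_centers[j, ] <- x[which.max(d[cbind(seq_len(n), assignment)]), ]
      }
    }
    shift <- sqrt(max(rowSums((new_centers - centers)^2)))
    centers <- new_centers
    if (shift < tol) break
  }
  list(centers = centers, assignment = assignment, n_iter = iter)
}

mean_silhouette <- function(x, assignment) {
  n <- nrow(x)
  k <- length(unique(assignment))
  if (k < 2 || n < 3) return(NA_real_)
  dm <- as.matrix(stats::dist(x))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- assignment == assignment[i]
    if (sum(own) == 1) { s[i] <- 0; next }
    a_i <- sum(dm[i, own]) / (sum(own) - 1)
    b_i <- min(vapply(setdiff(unique(assignment), assignment[i]), function(cl) {
      mean(dm[i, assignment == cl])
    }, numeric(1)))
    s[i] <- (b_i - a_i) / max(a_i, b_i)
  }
  mean(s)
}

#' k-means with k-means++ seeding and silhouette-selected k
#'
#' For each candidate k (capped at n - 1 and at the number of distinct
#' points): deterministic k-means++ initialisation from the seed, Lloyd
#' iterations to convergence (max centroid shift < 1e-6 or 300 iterations);
#' the k with the highest mean silhouette wins (ties to the smaller k).
#' All-identical inputs yield a k = 1 model.
#'
#' @param x numeric matrix of (standardised) feature vectors, one row per
#'   event.
#' @param k_range candidate cluster counts (default 2:6).
#' @param seed integer seed; identical `(x, seed)` give identical models.
#' @return list with `k`, `centroids`, `assignment`, `silhouette`, `seed`,
#'   `n_iter` (class `cluster_model`).
#' @export
kmeans_improved <- function(x, k_range = 2:6, seed = 1) {
  x <- as.matrix(x)
  if (nrow(x) == 0) stop("kmeans_improved: empty input")
  n_distinct <- nrow(unique(x))
  k_range <- k_range[k_range <= min(nrow(x) - 1, n_distinct)]
  if (n_distinct == 1 || length(k_range) == 0) {
    return(structure(list(k = 1L, centroids = x[1, , drop = FALSE],
                          assignment = rep(1L, nrow(x)),
                          silhouette = NA_real_, seed = seed, n_iter = 0L),
                     class = "cluster_model"))
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  best <- NULL
  for (k in sort(k_range)) {
    set.seed(seed + k)
    fit <- lloyd(x, kmeanspp_init(x, k))
    sil <- mean_silhouette(x, fit$assignment)
    if (is.null(best) || (!is.na(sil) && sil > best$silhouette)) {
      best <- list(k = as.integer(k), centroids = fit$centers,
                   assignment = fit$assignment, silhouette = sil,
                   seed = seed, n_iter = fit$n_iter)
    }
  }
  structure(best, class = "cluster_model")
}

#' Label events against a labelled reference
#'
#' An event is labelled `"true"` if it overlaps (by at least
#' `match_fraction` of the shorter event) any reference event labelled true,
#' else `"false"` if it overlaps any reference event labelled false, else
#' `"unknown"`.
#'
#' @param events events to label.
#' @param reference labelled `event_set` (e.g. generator ledger or the
#'   concatenation of a consensus truth's true and false sets).
#' @param match_fraction minimum overlap fraction.
#' @param unmatched label for events matching nothing: `"unknown"` for a
#'   partial reference (expert consensus screens only what experts marked),
#'   `"false"` for a complete one (a synthetic ledger knows every true
#'   spindle, so an unmatched event is a non-spindle).
#' @return character vector of labels aligned with `events` rows.
#' @export
label_events <- function(events, reference, match_fraction = 0.2,
                         unmatched = c("unknown", "false")) {
  unmatched <- match.arg(unmatched)
  n <- nrow(events)
  labels <- rep(unmatched, n)
  if (n == 0 || nrow(reference) == 0) return(labels)
  for (i in seq_len(n)) {
    same <- reference$channel == events$channel[i]
    if (!any(same)) next
    fr <- overlap_fraction_vec(events$onset_s[i], events$offset_s[i],
                               reference$onset_s[same], reference$offset_s[same])
    ref_lab <- reference$label[same]
    if (any(fr >= match_fraction & ref_lab == "true")) {
      labels[i] <- "true"
    } else if (any(fr >= match_fraction & ref_lab == "false")) {
      labels[i] <- "false"
    }
  }
  labels
}

#' Discard clusters dominated by labelled non-spindles
#'
#' A cluster is discarded iff, among its labelled members, the proportion
#' labelled false is strictly greater than `reject_fraction`. Clusters with
#' no labelled members are kept.
#'
#' @param model a `cluster_model` from [kmeans_improved()].
#' @param events the clustered events (rows aligned with the model's
#'   assignment).
#' @param labels character vector over `true`/`false`/`unknown`, aligned with
#'   `events`.
#' @param reject_fraction rejection threshold (default 0.5).
#' @return the kept events (`event_set`).
#' @export
reject_clusters <- function(model, events, labels, reject_fraction = 0.5) {
  keep_cluster <- vapply(seq_len(max(model$assignment)), function(cl) {
    lab <- labels[model$assignment == cl]
    lab <- lab[lab != "unknown"]
    if (length(lab) == 0) return(TRUE)
    mean(lab == "false") <= reject_fraction
  }, logical(1))
  kept <- events[keep_cluster[model$assignment], , drop = FALSE]
  validate_events(kept)
}

#' Fuse two detectors' outputs into the final spindle set
#'
#' The full fusion pipeline: partition into overlap/unique sets, resolve
#' overlap chains to their longest member, extract (amplitude, mean
#' frequency) features of unique events, cluster them with
#' [kmeans_improved()], reject clusters dominated by labelled non-spindles,
#' and return the union of the overlap representatives and the surviving
#' unique events, restamped `source = "fusion"`.
#'
#' Labels come from `reference`: an event set with a `label` column (the
#' synthetic generator's ledger, or a consensus truth via
#' [consensus_reference()]). A reference carrying attribute
#' `complete = TRUE` (the generator's ledger does) labels unmatched unique
#' events `"false"`; otherwise they stay `"unknown"` and do not vote in the
#' cluster rejection. Without a reference, rejection is skipped with a
#' warning and all unique events are kept.
#'
#' @param recording an [eeg_recording()] (for feature extraction).
#' @param setA,setB the wavelet and RMS event sets.
#' @param reference optional labelled `event_set`.
#' @param config run configuration (see [default_config()]).
#' @return fused `event_set` with `source = "fusion"`.
#' @export
fuse_detections <- function(recording, setA, setB, reference = NULL,
                            config = default_config()) {
  parts <- partition_detections(setA, setB)
  uniq <- parts$unique
  if (nrow(uniq) > 0) {
    uniq <- event_features(recording, uniq)
    if (is.null(reference)) {
      warning("no labelled reference: cluster rejection skipped, keeping all unique events")
    } else {
      unmatched <- if (isTRUE(attr(reference, "complete"))) "false" else "unknown"
      labels <- label_events(uniq, reference, config$evaluation$match_fraction,
                             unmatched = unmatched)
      if (nrow(uniq) >= 2) {
        feats <- standardize_features(cbind(amplitude = uniq$amplitude_pp_uV,
                                            frequency = uniq$mean_freq_hz))
        model <- kmeans_improved(feats, config$fusion$k_min:config$fusion$k_max,
                                 seed = config$fusion$seed)
        uniq <- reject_clusters(model, uniq, labels, config$fusion$reject_fraction)
      } else {
        uniq <- uniq[labels != "false", , drop = FALSE]
      }
    }
  }
  out <- bind_events(parts$overlap, uniq)
  if (nrow(out) > 0) out$source <- "fusion"
  validate_events(out)
}
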