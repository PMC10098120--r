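test_that("partition routes overlapping pairs and isolated events correctly", {
  a <- ev(10.0, 10.8, source = "wavelet")
  b <- ev(10.5, 11.6, source = "rms")
  p <- partition_detections(a, b)
  expect_equal(nrow(p$overlap), 1)
  expect_equal(p$overlap$onset_s, 10.5)        # longer event wins
  expect_equal(p$overlap$offset_s, 11.6)
  expect_equal(nrow(p$unique), 0)

  p2 <- partition_detections(ev(10, 11, source = "wavelet"),
                             ev(20, 21, source = "rms"))
  expect_equal(nrow(p2$overlap), 0)
  expect_equal(nrow(p2$unique), 2)

  b5 <- ev(seq(10, 50, 10), seq(10.8, 50.8, 10), source = "rms")
  p3 <- partition_detections(spindle_events(), b5)
  expect_equal(nrow(p3$overlap), 0)
  expect_equal(nrow(p3$unique), 5)
})

test_that("every input event is covered exactly once by the partition", {
  set.seed(17)
  for (i in 1:20) {
    on_a <- sort(runif(8, 0, 100)); on_b <- sort(runif(8, 0, 100))
    a <- validate_events(data.frame(channel = "C3", onset_s = on_a,
                                    offset_s = on_a + runif(8, 0.5, 2),
                                    source = "wavelet"))
    b <- validate_events(data.frame(channel = "C3", onset_s = on_b,
                                    offset_s = on_b + runif(8, 0.5, 2),
                                    source = "rms"))
    p <- partition_detections(a, b)
    # representatives + unique events never exceed the input, and each
    # representative is one of the inputs
    all_in <- rbind(as.data.frame(a), as.data.frame(b))
    reps <- as.data.frame(p$overlap)
    expect_true(all(reps$onset_s %in% all_in$onset_s))
    expect_true(all(p$unique$onset_s %in% all_in$onset_s))
    expect_lte(nrow(p$overlap) + nrow(p$unique), nrow(a) + nrow(b))
  }
})

test_that("resolve_overlap prefers duration, then onset, then wavelet", {
  g <- rbind(data.frame(channel = "C3", onset_s = 10, offset_s = 10.8,
                        source = "wavelet"),
             data.frame(channel = "C3", onset_s = 10.4, offset_s = 11.5,
                        source = "rms"))
  expect_equal(resolve_overlap(g)$offset_s, 11.5)

  tie <- rbind(data.frame(channel = "C3", onset_s = 10.2, offset_s = 11.2,
                          source = "rms"),
               data.frame(channel = "C3", onset_s = 10.0, offset_s = 11.0,
                          source = "wavelet"))
  expect_equal(resolve_overlap(tie)$onset_s, 10.0)

  same <- rbind(data.frame(channel = "C3", onset_s = 10, offset_s = 11,
                           source = "rms"),
                data.frame(channel = "C3", onset_s = 10, offset_s = 11,
                           source = "wavelet"))
  expect_equal(resolve_overlap(same)$source, "wavelet")

  chain <- data.frame(channel = "C3", onset_s = c(10, 10.5, 11.2),
                      offset_s = c(10.6, 11.4, 11.9),
                      source = "wavelet")
  expect_equal(resolve_overlap(chain)$offset_s - resolve_overlap(chain)$onset_s, 0.9)
  expect_error(resolve_overlap(chain[1, ]), ">= 2")
})

test_that("feature standardisation uses sample SD and handles degeneracy", {
  z <- spindlefusion:::standardize_features(cbind(amp = c(20, 40), f = c(13, 13)))
  expect_equal(z[, "amp"], c(-1, 1) / sqrt(2), tolerance = 1e-12)  # +/- 0.707
  expect_equal(z[, "f"], c(0, 0))                                  # zero SD
  z1 <- spindlefusion:::standardize_features(cbind(amp = 30, f = 13))
  expect_equal(as.numeric(z1), c(0, 0))                            # single event
})

test_that("k-means recovers two blobs and is deterministic", {
  set.seed(99)
  x <- rbind(matrix(rnorm(200, -2, 0.3), ncol = 2),
             matrix(rnorm(200, 2, 0.3), ncol = 2))
  truth <- rep(1:2, each = 100)
  m <- kmeans_improved(x, 2:6, seed = 7)
  expect_equal(m$k, 2)
  agreement <- max(mean((m$assignment == 1) == (truth == 1)),
                   mean((m$assignment == 2) == (truth == 1)))
  expect_gte(agreement, 0.99)

  m2 <- kmeans_improved(x, 2:6, seed = 7)
  expect_identical(m[names(m) != "n_iter"], m2[names(m2) != "n_iter"])

  same <- matrix(1, nrow = 5, ncol = 2)
  m3 <- kmeans_improved(same, 2:6, seed = 1)
  expect_equal(m3$k, 1)
  expect_equal(as.numeric(m3$centroids), c(1, 1))
  expect_error(kmeans_improved(matrix(numeric(0), ncol = 2)), "empty")
})

test_that("mean silhouette matches a hand-computed case", {
  # points 0, 1, 5 on a line; clusters {0,1} and {5}
  x <- matrix(c(0, 1, 5), ncol = 1)
  s <- spindlefusion:::mean_silhouette(x, c(1, 1, 2))
  # s(0) = (5-1)/5, s(1) = (4-1)/4, singleton s(5) = 0 by convention
  expect_equal(s, mean(c(4 / 5, 3 / 4, 0)), tolerance = 1e-12)
})

test_that("cluster rejection follows the strict-majority-false rule", {
  events <- ev(seq(0, 95, 5), seq(0.8, 95.8, 5))
  n <- nrow(events)
  model <- structure(list(k = 2L, assignment = rep(1:2, each = n / 2)),
                     class = "cluster_model")
  labels <- c(rep(c("false", "true"), c(8, 2)),       # cluster 1: 80% false
              rep("unknown", n / 2))                  # cluster 2: unlabelled
  kept <- reject_clusters(model, events, labels)
  expect_equal(nrow(kept), n / 2)                     # cluster 1 dropped

  labels2 <- c(rep(c("false", "true"), 5), rep("unknown", n / 2))  # exactly 50%
  expect_equal(nrow(reject_clusters(model, events, labels2)), n)   # kept
})

test_that("event labelling distinguishes partial and complete references", {
  reference <- validate_events(data.frame(
    channel = "C3", onset_s = c(10, 30), offset_s = c(11, 31),
    source = "truth", label = c("true", "false")))
  events <- ev(c(10.2, 30.1, 60), c(11.1, 31.2, 61))
  expect_equal(label_events(events, reference),
               c("true", "false", "unknown"))
  expect_equal(label_events(events, reference, unmatched = "false"),
               c("true", "false", "false"))
})

test_that("fusion equals the overlap set when detectors agree, never invents", {
  truth_on <- seq(10, 90, 10)
  a <- ev(truth_on, truth_on + 1, source = "wavelet")
  b <- ev(truth_on, truth_on + 1, source = "rms")
  rec <- tone_recording(duration_s = 100)
  fused <- fuse_detections(rec, a, b, reference = NULL)
  expect_equal(nrow(fused), length(truth_on))
  expect_true(all(fused$source == "fusion"))
  expect_true(all(fused$onset_s %in% truth_on))

  # unique set empty branch
  p <- partition_detections(a, b)
  expect_equal(nrow(p$unique), 0)
  expect_equal(fused$onset_s, p$overlap$onset_s)
})

test_that("fusion on a seeded subject beats the components' precision", {
  subj <- rendered_subject(seed = 1)
  rec <- subj$recording
  win <- scoring_window(subj$hypnogram, recording_duration(rec))
  p <- detector_params()
  w <- detect_wavelet(rec$samples$C3, rec$sampling_rate, p, "C3", win)
  r <- detect_rms(rec$samples$C3, rec$sampling_rate, p, "C3", win)
  fused <- fuse_detections(rec, w, r, reference = subj$truth)
  truth <- subj$truth[subj$truth$channel == "C3", ]
  expect_gte(precision_of(fused, truth),
             max(precision_of(w, truth), precision_of(r, truth)) - 0.02)
  # determinism: identical inputs and seed give the identical set
  fused2 <- fuse_detections(rec, w, r, reference = subj$truth)
  expect_identical(as.data.frame(fused), as.data.frame(fused2))
  # fusion never invents events
  pools <- c(partition_detections(w, r)$overlap$onset_s, w$onset_s, r$onset_s)
  expect_true(all(fused$onset_s %in% pools))
})

test_that("fusion without labels keeps everything but warns", {
  a <- ev(10, 11, source = "wavelet")
  b <- ev(50, 51, source = "rms")
  rec <- tone_recording(duration_s = 60)
  expect_warning(fused <- fuse_detections(rec, a, b, reference = NULL),
                 "rejection skipped")
  expect_equal(nrow(fused), 2)
})
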