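test_that("density is the straight quotient and rejects bad denominators", {
  expect_equal(spindle_density(480, 480), 1.0)
  expect_equal(round(spindle_density(356, 152.5), 3), 2.334)
  expect_equal(spindle_density(0, 100), 0)
  expect_equal(spindle_density(10, 5), 2 * spindle_density(5, 5))
  expect_error(spindle_density(5, 0), "positive")
})

test_that("peak-to-peak amplitude matches the sine closed form and scales", {
  rec <- tone_recording(freq_hz = 13, peak_uV = 20, duration_s = 4)
  a <- amplitude_pp(rec, "C3", 1, 2.5)
  expect_lt(abs(a - 40) / 40, 0.02)

  rec3 <- rec; rec3$samples$C3 <- 3 * rec3$samples$C3
  expect_equal(amplitude_pp(rec3, "C3", 1, 2.5), 3 * a, tolerance = 1e-9)

  silent <- eeg_recording("z", list(C3 = rep(0, 1024)), 256)
  expect_equal(amplitude_pp(silent, "C3", 1, 2), 0)
  expect_error(amplitude_pp(rec, "C3", 3, 5), "outside")
  expect_error(amplitude_pp(rec, "Cz", 1, 2), "not in recording")
})

test_that("mean frequency resolves tones and symmetric mixtures", {
  rec <- tone_recording(freq_hz = 13, peak_uV = 20, duration_s = 4)
  expect_lt(abs(mean_frequency(rec, "C3", 1, 2.5) - 13), 0.25)

  rate <- 256
  tt <- seq(0, 4 - 1 / rate, by = 1 / rate)
  mix <- sin(2 * pi * 12 * tt) + sin(2 * pi * 14 * tt)
  rec2 <- eeg_recording("m", list(C3 = mix), rate)
  expect_lt(abs(mean_frequency(rec2, "C3", 1, 3) - 13), 0.25)

  expect_error(mean_frequency(rec, "C3", 1, 1.3), "0.5")
})

test_that("generator spindles land in their programmed histogram band", {
  rate <- 256
  burst <- gen_spindle(11.5, 40, 1.2, rate)
  x <- rep(0, 10 * rate)
  x[(2 * rate):(2 * rate + length(burst) - 1)] <- burst
  rec <- eeg_recording("g", list(C3 = x), rate)
  f <- mean_frequency(rec, "C3", 2, 3.2)
  expect_lt(abs(f - 11.5), 0.25)
  h <- spindle_histograms(f, 40)
  expect_equal(unname(h$frequency["[11,12)"]), 1)
})

test_that("histograms use the fixed left-closed bins and sum to one", {
  h <- spindle_histograms(c(11.5, 12.5, 13.5, 14.5), c(5, 15, 35, 75))
  expect_equal(unname(h$frequency), c(0.25, 0.25, 0.25, 0.25, 0))
  expect_equal(unname(h$amplitude[c("[0,10)", "[10,20)", "[30,40)", "[70,Inf)")]),
               rep(0.25, 4))
  expect_equal(sum(h$frequency), 1)
  expect_equal(sum(h$amplitude), 1)

  edge <- spindle_histograms(13.0, 35)
  expect_equal(unname(edge$frequency["[13,14)"]), 1)   # left-closed rule
  expect_equal(unname(edge$amplitude["[30,40)"]), 1)
  top <- spindle_histograms(16.0, 10)
  expect_equal(unname(top$frequency["[15,16]"]), 1)    # closed upper edge

  h0 <- spindle_histograms(numeric(), numeric())
  expect_equal(h0$n, 0)
  expect_true(all(h0$frequency == 0))
})

test_that("symmetric channel counts report right-minus-left differences", {
  events <- validate_events(data.frame(
    channel = rep(c("C3", "C4", "F3", "F4"), c(100, 113, 50, 50)),
    onset_s = seq_len(313) * 10, offset_s = seq_len(313) * 10 + 1))
  sc <- symmetric_counts(events)
  expect_equal(sc$difference[sc$left == "C3"], 13)
  expect_equal(sc$difference[sc$left == "F3"], 0)
  expect_error(symmetric_counts(events[events$channel != "F4", ]), "F3/F4")

  one_sided <- validate_events(data.frame(
    channel = "C3", onset_s = 1:5, offset_s = 2:6))
  # C4 recorded but empty -> difference is the negated full count
  sc2 <- symmetric_counts(one_sided, pairs = list(c("C3", "C4")),
                          channels = c("C3", "C4"))
  expect_equal(sc2$difference, -5)
  # C4 genuinely missing from the recording -> error naming the pair
  expect_error(symmetric_counts(one_sided, pairs = list(c("C3", "C4"))), "C3/C4")
})

test_that("feature summary pulls everything together for one subject", {
  subj <- rendered_subject(seed = 8)
  truth <- subj$truth[subj$truth$channel == "C3", ][1:10, ]
  fs <- feature_summary(subj$recording, truth, minutes = 20)
  expect_equal(fs$n_spindles, 10)
  expect_equal(fs$density_per_min, 0.5)
  expect_true(fs$mean_frequency_hz > 11 && fs$mean_frequency_hz < 16)
  expect_gt(fs$mean_amplitude_uV, 0)
})

test_that("detector-emitted events stay inside the analysis band", {
  subj <- rendered_subject(seed = 1)
  rec <- subj$recording
  win <- scoring_window(subj$hypnogram, recording_duration(rec))
  found <- detect_rms(rec$samples$C3, rec$sampling_rate, detector_params(),
                      "C3", win)
  feats <- event_features(rec, found)
  expect_true(all(feats$mean_freq_hz >= 11 & feats$mean_freq_hz <= 16))
  expect_true(all(feats$amplitude_pp_uV > 0))
})
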