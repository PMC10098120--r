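test_that("consensus implements the two-of-three rules on toy sets", {
  a <- ev(c(10, 50), c(11, 51), source = "expert")
  b <- ev(c(10.1, 80), c(11.1, 81), source = "expert")
  c_ <- ev(120, 121, source = "expert")
  ct <- consensus(list(a, b, c_))
  # only 10-11 is supported by two experts
  expect_equal(nrow(ct$true_set), 1)
  expect_equal(ct$true_set$onset_s, 10)       # union of matched intervals
  expect_equal(ct$true_set$offset_s, 11.1)
  # unsupported events (50, 80, 120) form the non-spindle set
  expect_equal(sort(ct$false_set$onset_s), c(50, 80, 120))

  # identical interval in all three -> exactly one true event
  same <- ev(10, 11, source = "expert")
  ct3 <- consensus(list(same, same, same))
  expect_equal(nrow(ct3$true_set), 1)
  expect_equal(nrow(ct3$false_set), 0)

  expect_error(consensus(list(a, b)), "exactly 3")
})

test_that("consensus(A, A, A) reproduces A with an empty false set", {
  set.seed(23)
  on <- sort(runif(12, 0, 300)); on <- on[c(TRUE, diff(on) > 3)]
  a <- ev(on, on + runif(length(on), 0.5, 1.5), source = "expert")
  ct <- consensus(list(a, a, a))
  expect_equal(ct$true_set$onset_s, a$onset_s)
  expect_equal(ct$true_set$offset_s, a$offset_s)
  expect_equal(nrow(ct$false_set), 0)
})

test_that("match_events is greedy one-to-one with the count identities", {
  truth <- ev(seq(10, 100, 10), seq(10.8, 100.8, 10))
  m <- match_events(truth, truth)
  expect_equal(unlist(m), c(tp = 10, fp = 0, fn = 0))

  m2 <- match_events(spindle_events(), ev(seq(1, 7), seq(1.6, 7.6)))
  expect_equal(unlist(m2), c(tp = 0, fp = 0, fn = 7))

  pred <- ev(c(10.0, 10.4), c(10.6, 11.0))
  m3 <- match_events(pred, ev(10, 11))
  expect_equal(unlist(m3), c(tp = 1, fp = 1, fn = 0))

  set.seed(41)
  for (i in 1:10) {
    p_on <- sort(runif(15, 0, 200)); t_on <- sort(runif(12, 0, 200))
    pred <- ev(p_on, p_on + runif(15, 0.5, 1.5))
    tru <- ev(t_on, t_on + runif(12, 0.5, 1.5))
    m <- match_events(pred, tru)
    expect_equal(m$tp + m$fn, nrow(tru))
    expect_equal(m$tp + m$fp, nrow(pred))
  }
})

test_that("binwise confusion counts bins at 50% coverage", {
  win <- structure(list(start_s = 0, end_s = 60), class = "scoring_window")
  e <- ev(10, 11)
  b <- binwise_confusion(e, e, win, bin_s = 0.5)
  expect_equal(unlist(b), c(tp = 2, fp = 0, fn = 0, tn = 118))

  full <- ev(0, 60)
  b2 <- binwise_confusion(full, spindle_events(), win)
  expect_equal(b2$fp, 120)
  b3 <- binwise_confusion(spindle_events(), spindle_events(), win)
  expect_equal(b3$tn, 120)
  expect_error(binwise_confusion(ev(59, 61), e, win), "outside")
})

test_that("metrics match hand-computed confusion tables", {
  m <- metrics(list(tp = 9, fp = 1, fn = 1, tn = 89))
  expect_equal(unname(m["recall"]), 90)
  expect_equal(unname(m["precision"]), 90)
  expect_equal(unname(m["specificity"]), 100 * 89 / 90, tolerance = 1e-10)
  expect_equal(unname(m["accuracy"]), 98)
  expect_equal(unname(m["f1"]), 90)

  perfect <- metrics(list(tp = 10, fp = 0, fn = 0, tn = 90))
  expect_true(all(perfect == 100))

  zero <- metrics(list(tp = 0, fp = 0, fn = 5, tn = 95))
  expect_equal(unname(zero["recall"]), 0)
  expect_true("precision" %in% attr(zero, "flagged"))
  expect_error(metrics(list(tp = 0, fp = 0, fn = 0, tn = 0)), "zero")
})

test_that("variance table uses the n-1 convention and is shift-invariant", {
  d <- data.frame(subject_id = 1:3, recall = c(80, 90, 100))
  expect_equal(unname(variance_table(d)["recall"]), 100)
  d$recall <- d$recall + 7
  expect_equal(unname(variance_table(d)["recall"]), 100)
  expect_equal(unname(variance_table(
    data.frame(subject_id = 1:2, f1 = c(85, 95)))["f1"]), 50)
  expect_equal(unname(variance_table(
    data.frame(subject_id = 1:4, f1 = rep(60, 4)))["f1"]), 0)
  expect_error(variance_table(data.frame(subject_id = 1, f1 = 50)), ">= 2")
})

test_that("compare_detectors reports all three methods and warns on n = 1", {
  subj <- rendered_subject(seed = 6)
  expect_warning(rep1 <- compare_detectors(list(subj)), "single-subject")
  expect_setequal(rep1$per_subject$method, c("wavelet", "rms", "fusion"))
  expect_true(all(rep1$per_subject$recall >= 0 & rep1$per_subject$recall <= 100))
  expect_true(all(is.na(rep1$summary$recall_var)))
  expect_error(compare_detectors(list()), "empty cohort")
})
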