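test_that("background noise hits its RMS target deterministically", {
  x <- gen_background(60, 256, rms_uV = 15, alpha = 1, seed = 5)
  r <- sqrt(mean(x^2))
  expect_gte(r, 14.85); expect_lte(r, 15.15)
  expect_identical(x, gen_background(60, 256, rms_uV = 15, alpha = 1, seed = 5))
})

test_that("alpha = 0 background has a flat spectrum", {
  x <- gen_background(600, 256, rms_uV = 10, alpha = 0, seed = 6)
  # Welch-style estimate: mean periodogram over 8 s segments
  seg_len <- 8 * 256
  segs <- matrix(x[seq_len(seg_len * floor(length(x) / seg_len))],
                 nrow = seg_len)
  pows <- apply(segs, 2, function(s) Mod(stats::fft(s))^2 / seg_len)
  freqs <- (seq_len(seg_len) - 1) * 256 / seg_len
  p_low <- mean(pows[freqs >= 1 & freqs <= 10, ])
  p_high <- mean(pows[freqs >= 40 & freqs <= 49, ])
  expect_lt(abs(p_low / p_high - 1), 0.2)
})

test_that("rendered spindles honour amplitude, frequency and bounds", {
  burst <- gen_spindle(13, 40, 1.0, 256)
  pp <- max(burst) - min(burst)
  expect_gte(pp, 38); expect_lte(pp, 42)
  expect_error(gen_spindle(13, 40, 0.4, 256), "duration")
  expect_error(gen_spindle(10, 40, 1.0, 256), "frequency")
})

test_that("subject generation respects density, duration and non-overlap", {
  params <- cohort_params(duration_min = 60, channels = "C3")
  params$density_range$DS <- c(2, 2)      # pin the density at 2 per min
  subj <- gen_subject(params, "DS", "D1", seed = 12, render = FALSE)
  n <- nrow(subj$truth)
  expect_gte(n, 76); expect_lte(n, 164)   # Poisson(120) +/- 4 sd

  durs <- event_duration(subj$truth)
  expect_true(all(durs >= 0.5 & durs <= 1.5))
  by_ch <- split(as.data.frame(subj$truth), subj$truth$channel)
  for (d in by_ch) {
    if (nrow(d) > 1) expect_true(all(d$onset_s[-1] >= d$offset_s[-nrow(d)]))
  }

  subj2 <- gen_subject(params, "DS", "D1", seed = 12, render = FALSE)
  expect_identical(as.data.frame(subj$truth), as.data.frame(subj2$truth))
  expect_identical(subj$subject, subj2$subject)
})

test_that("event marginals match their specified distributions (KS)", {
  params <- cohort_params(duration_min = 480, channels = "C3")
  params$density_range$NS <- c(2.1, 2.1)
  subj <- gen_subject(params, "NS", "N1", seed = 77, render = FALSE)
  tr <- subj$truth
  expect_gt(nrow(tr), 800)

  # duration ~ truncated normal (0.9, 0.25) on [0.5, 1.5]
  pn <- function(q) stats::pnorm(q, 0.9, 0.25)
  trunc_cdf <- function(q) (pn(pmin(pmax(q, 0.5), 1.5)) - pn(0.5)) / (pn(1.5) - pn(0.5))
  ks_d <- suppressWarnings(stats::ks.test(event_duration(tr), trunc_cdf))
  expect_gt(ks_d$p.value, 0.01)

  # frequency ~ 70% U[12,14] + 10% U[11,12] + 20% U[14,16]
  freq_cdf <- function(q) {
    q <- pmin(pmax(q, 11), 16)
    0.1 * pmin(1, pmax(0, q - 11)) +
      0.7 * pmin(1, pmax(0, (q - 12) / 2)) +
      0.2 * pmin(1, pmax(0, (q - 14) / 2))
  }
  ks_f <- suppressWarnings(stats::ks.test(tr$mean_freq_hz, freq_cdf))
  expect_gt(ks_f$p.value, 0.01)

  # amplitude ~ U[20, 60] for NS
  ks_a <- suppressWarnings(stats::ks.test(tr$amplitude_pp_uV, "punif", 20, 60))
  expect_gt(ks_a$p.value, 0.01)
})

test_that("perfect experts reproduce the truth through consensus", {
  subj <- rendered_subject(seed = 3)
  params <- subj$params
  perfect <- params
  perfect$expert <- list(p_mid_uV = -1e9, p_scale_uV = 1, jitter_sd_s = 0,
                         fp_per_min = 0)
  ex <- gen_experts(subj$truth, 1200, perfect, seed = 4)
  for (e in ex) {
    expect_equal(e$onset_s, subj$truth$onset_s)
    expect_equal(e$offset_s, subj$truth$offset_s)
  }
  ct <- consensus(ex)
  expect_equal(nrow(ct$true_set), nrow(subj$truth))
  expect_equal(nrow(ct$false_set), 0)

  blind <- params
  blind$expert$p_mid_uV <- 1e9
  blind$expert$fp_per_min <- 0
  ex0 <- gen_experts(subj$truth, 1200, blind, seed = 4)
  expect_true(all(vapply(ex0, nrow, 1L) == 0))
})

test_that("default experts give high-recall consensus (two-of-three)", {
  subj <- rendered_subject(seed = 9)
  ct <- consensus(subj$experts)
  expect_gte(recall_of(ct$true_set, subj$truth), 0.95)
})

test_that("cohort generation is deterministic and group-structured", {
  co <- gen_cohort(cohort_params(duration_min = 20, channels = "C3", seed = 42),
                   render = FALSE)
  expect_equal(nrow(co$subjects), 30)
  expect_equal(sum(co$subjects$group == "DS"), 20)
  dens <- co$subjects$true_density_per_min
  expect_lt(mean(dens[co$subjects$group == "DS"]),
            mean(dens[co$subjects$group == "NS"]))

  co2 <- gen_cohort(cohort_params(duration_min = 20, channels = "C3", seed = 42),
                    render = FALSE)
  expect_identical(co$subjects, co2$subjects)
})

test_that("nulled coupling leaves the correlation centred at zero", {
  rs <- vapply(1:100, function(sd) {
    params <- null_coupling_params(
      cohort_params(duration_min = 20, channels = "C3", seed = sd))
    co <- gen_cohort(params, render = FALSE)
    pearson(co$subjects$psqi, co$subjects$true_density_per_min)$r
  }, numeric(1))
  # under the null at n = 30, E|r| = sqrt(2 / (pi (n - 2))) ~ 0.148; test the
  # centring directly and bound |r| well below the coupled world's ~0.86
  expect_lt(abs(mean(rs)), 0.06)
  expect_lt(mean(abs(rs)), 0.25)
})
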