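# Digital Butterworth band-pass design and zero-phase filtering.
#
# No DSP package ships with the target environment, so the classical design
# chain is implemented here: analog Butterworth prototype -> low-pass to
# band-pass transform -> bilinear transform with frequency pre-warping ->
# polynomial transfer function. Verified in tests against the closed-form
# transfer magnitude.

# Analog prototype poles of an order-n Butterworth low-pass (unit cutoff).
butter_prototype <- function(n) {
  k <- seq_len(n)
  exp(1i * pi * (2 * k + n - 1) / (2 * n))
}

poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (root in r) p <- c(p, 0) - c(0, p * root)
  p
}

#' Design a digital Butterworth band-pass filter
#'
#' @param order prototype order (the band-pass has `2 * order` poles; the
#'   default 4 gives an 8th-order filter, 16th-order effective after
#'   forward-backward application).
#' @param low_hz,high_hz band edges in Hz.
#' @param rate sampling rate in Hz; must exceed `2 * high_hz`.
#' @return list with numerator `b` and denominator `a` coefficients.
#' @export
butter_bandpass <- function(low_hz, high_hz, rate, order = 4) {
  if (rate <= 2 * high_hz) {
    stop("sampling rate ", rate, " Hz too low for a ", high_hz, " Hz band edge")
  }
  if (low_hz <= 0 || low_hz >= high_hz) stop("invalid band edges")
  fs2 <- 2 * rate
  # pre-warped analog edge frequencies
  wl <- fs2 * tan(pi * low_hz / rate)
  wh <- fs2 * tan(pi * high_hz / rate)
  w0 <- sqrt(wl * wh)
  bw <- wh - wl

  proto <- butter_prototype(order)
  # low-pass -> band-pass: each prototype pole p yields the two roots of
  # s^2 - (p * bw) s + w0^2 = 0
  pb <- proto * bw
  disc <- sqrt(pb^2 / 4 - w0^2 + 0i)
  poles <- c(pb / 2 + disc, pb / 2 - disc)
  zeros <- rep(0 + 0i, order)           # plus `order` zeros at infinity
  gain <- bw^order

  # bilinear transform
  pd <- (fs2 + poles) / (fs2 - poles)
  zd <- (fs2 + zeros) / (fs2 - zeros)
  gain_d <- gain * Re(prod(fs2 - zeros) / prod(fs2 - poles))
  zd <- c(zd, rep(-1 + 0i, length(pd) - length(zd)))

  b <- Re(poly_from_roots(zd)) * gain_d
  a <- Re(poly_from_roots(pd))
  list(b = b, a = a)
}

# Transfer magnitude |H(e^{i 2 pi f / rate})| of a digital filter; used by the
# tests as the independent stop-band oracle.
filter_gain <- function(coef, freq_hz, rate) {
  z <- exp(-1i * 2 * pi * freq_hz / rate)
  pow <- seq_along(coef$b) - 1
  num <- vapply(z, function(zz) sum(coef$b * zz^pow), complex(1))
  pow <- seq_along(coef$a) - 1
  den <- vapply(z, function(zz) sum(coef$a * zz^pow), complex(1))
  Mod(num / den)
}

# Single-pass IIR filtering (direct form), built from the two C-level
# stats::filter primitives: FIR part by convolution, AR part recursively.
lfilter <- function(b, a, x) {
  b <- b / a[1]
  a <- a / a[1]
  nb <- length(b)
  xp <- c(rep(0, nb - 1), x)
  v <- stats::filter(xp, b, method = "convolution", sides = 1)
  v <- as.numeric(v[nb:length(xp)])
  if (length(a) > 1) {
    v <- as.numeric(stats::filter(v, -a[-1], method = "recursive"))
  }
  v
}

# Second-order-section factorisation of the band-pass: conjugate pole pairs
# become biquad denominators, the 2*order zeros at +/-1 give (z^2 - 1)
# numerators, and the gain is spread evenly. Cascaded biquads keep the
# numerical error orders of magnitude below the expanded polynomial form.
butter_bandpass_sos <- function(low_hz, high_hz, rate, order = 4) {
  if (rate <= 2 * high_hz) {
    stop("sampling rate ", rate, " Hz too low for a ", high_hz, " Hz band edge")
  }
  fs2 <- 2 * rate
  wl <- fs2 * tan(pi * low_hz / rate)
  wh <- fs2 * tan(pi * high_hz / rate)
  w0 <- sqrt(wl * wh); bw <- wh - wl
  pb <- butter_prototype(order) * bw
  disc <- sqrt(pb^2 / 4 - w0^2 + 0i)
  poles <- c(pb / 2 + disc, pb / 2 - disc)
  gain <- bw^order
  pd <- (fs2 + poles) / (fs2 - poles)
  gain_d <- gain * Re(fs2^order / prod(fs2 - poles))
  upper <- pd[Im(pd) >= 0]
  upper <- upper[order(Mod(upper))]
  g_sec <- abs(gain_d)^(1 / length(upper))
  sgn <- sign(gain_d)
  lapply(seq_along(upper), function(i) {
    p <- upper[i]
    g <- if (i == 1) g_sec * sgn else g_sec
    list(b = g * c(1, 0, -1),                       # zeros at +1 and -1
         a = c(1, -2 * Re(p), Mod(p)^2))
  })
}

# Zero-phase filtering through the biquad cascade: odd-reflection padding,
# forward pass, reversed pass. The pad (3 s or the signal length, whichever
# is smaller) absorbs the edge transient of the zero initial state.
filtfilt_butter <- function(sos, x, rate) {
  n <- length(x)
  pad <- min(n - 1, max(24, round(3 * rate)))
  if (pad < 1) stop("signal too short to filter")
  left <- 2 * x[1] - x[seq(pad + 1, 2)]
  right <- 2 * x[n] - x[seq(n - 1, n - pad)]
  y <- c(left, x, right)
  for (sec in sos) y <- lfilter(sec$b, sec$a, y)
  y <- rev(y)
  for (sec in sos) y <- lfilter(sec$b, sec$a, y)
  y <- rev(y)
  y[(pad + 1):(pad + n)]
}

#' Zero-phase sigma band-pass filter
#'
#' 4th-order Butterworth applied forward and backward (8th order, zero phase),
#' so event timestamps measured on the filtered trace stay aligned with the
#' raw signal.
#'
#' @param signal numeric vector in microvolts.
#' @param rate sampling rate in Hz.
#' @param low_hz,high_hz band edges (defaults: the 11-16 Hz sigma band).
#' @return filtered signal, same length as the input.
#' @export
bandpass <- function(signal, rate, low_hz = 11, high_hz = 16) {
  sos <- butter_bandpass_sos(low_hz, high_hz, rate, order = 4)
  if (length(signal) <= 24) {
    stop("signal too short for the filter order")
  }
  filtfilt_butter(sos, signal, rate)
}

#' Scoring window: up to 8 h from sleep onset
#'
#' Sleep onset is the start of the first epoch whose stage is not `W`; the
#' window extends 8 h or to the end of the hypnogram (or `total_s`, when the
#' recording is shorter), whichever comes first.
#'
#' @param hyp a [hypnogram()].
#' @param total_s optional recording duration in seconds capping the window.
#' @return list with `start_s`, `end_s`, `reason` (class `scoring_window`).
#' @export
scoring_window <- function(hyp, total_s = NULL) {
  stopifnot(inherits(hyp, "hypnogram"))
  first_sleep <- which(hyp$stages != "W")[1]
  if (is.na(first_sleep)) stop("all-wake hypnogram: no sleep onset")
  start_s <- (first_sleep - 1) * hyp$epoch_length_s
  end_s <- min(start_s + 8 * 3600, length(hyp$stages) * hyp$epoch_length_s)
  if (!is.null(total_s)) end_s <- min(end_s, total_s)
  if (end_s <= start_s) stop("empty scoring window")
  structure(list(start_s = start_s, end_s = end_s,
                 reason = "8 h from first non-wake epoch"),
            class = "scoring_window")
}

#' First sleep cycle window
#'
#' A sleep cycle starts on entry into NREM and ends on exit from REM. The
#' first cycle therefore runs from the first `N1`/`N2`/`N3` epoch to the end
#' of the first maximal contiguous REM run that begins after it.
#'
#' @param hyp a [hypnogram()].
#' @return `scoring_window` covering the first cycle.
#' @export
first_cycle <- function(hyp) {
  stopifnot(inherits(hyp, "hypnogram"))
  el <- hyp$epoch_length_s
  nrem_first <- which(hyp$stages %in% c("N1", "N2", "N3"))[1]
  if (is.na(nrem_first)) stop("first cycle incomplete: no NREM epoch")
  rem_after <- which(hyp$stages == "REM" & seq_along(hyp$stages) > nrem_first)
  if (length(rem_after) == 0) stop("first cycle incomplete: no REM after NREM")
  rem_start <- rem_after[1]
  rem_end <- rem_start
  while (rem_end < length(hyp$stages) && hyp$stages[rem_end + 1] == "REM") {
    rem_end <- rem_end + 1
  }
  structure(list(start_s = (nrem_first - 1) * el, end_s = rem_end * el,
                 reason = "first NREM epoch to end of first REM run"),
            class = "scoring_window")
}
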