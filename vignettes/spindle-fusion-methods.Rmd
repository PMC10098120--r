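---
title: "Fusion detection of sleep spindles: models, parameters, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fusion detection of sleep spindles: models, parameters, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(spindlefusion)
```

This vignette is the package's own account of its science: the detection and
fusion model and its assumptions, the parameters that matter and why they
have the defaults they have, what the synthetic generator does and does not
emulate, the numerical choices, and the places where the design was genuinely
open and a decision had to be made. Every empirical statement here is one the
test suite or `scripts/acceptance.R` computes itself.

## 1. The detection problem

A sleep spindle is a burst of 11–16 Hz oscillatory activity on the sleep EEG
lasting at least 0.5 s (typically 0.5–1.5 s). Detection is done per channel
over a *scoring window* that starts at the first non-wake epoch of the
hypnogram and extends at most 8 h — the windowing emulates the standard
practice of analysing a uniform amount of sleep from sleep onset. The first
*sleep cycle* — from the first NREM epoch to the end of the first contiguous
REM run — is windowed separately for the first-cycle analyses.

Both detectors convert the signal to a non-negative *activation series* and
threshold it **relative to the series' own statistics**, never in absolute
microvolts. This is the central robustness assumption: amplitude scales vary
across subjects, electrodes and montages, but the *ratio* of burst activation
to background activation does not. A consequence, enforced by property tests,
is that both detectors are exactly invariant to DC offsets and to positive
rescaling of the input.

### Morlet-wavelet envelope detector

The raw signal is convolved with a complex Morlet wavelet: a complex
exponential at centre frequency $f_0$ under a Gaussian envelope with
$\sigma_t = n_c / (2\pi f_0)$. With the default $f_0 = 13.5$ Hz (mid-sigma)
and $n_c = 7$ cycles, the wavelet's spectral full width covers the sigma band
without bleeding into alpha or beta. The magnitude of the convolution,
smoothed by a 0.1 s moving average, is the envelope; events are maximal runs
above `threshold_multiplier × median(envelope)`.

**Why a multiplier of 2.0.** The median envelope is dominated by background
(spindles occupy a few percent of sleep), so the multiplier expresses "how
many times the typical background sigma level must a burst reach". On the
package's stated synthetic world (15 µV RMS pink background; bursts of
15–60 µV peak-to-peak, i.e. envelope peaks roughly 5–25× the background
envelope median, Hann-tapered at the edges), a multiplier of 4.5 — a common
choice when thresholding *power* rather than amplitude envelopes — leaves
only the strongest bursts above threshold long enough to pass the 0.5 s
duration floor, and standalone recall collapses to 0.1–0.5. Calibrating on
envelope statistics from both groups (seeds disjoint from any acceptance
seed) puts the knee at 2.0: the weakest bursts cross for most of their
duration while background excursions rarely persist 0.5 s. The value is
config-exposed (`wavelet.threshold_multiplier`).

### Small-window RMS detector

The signal is band-passed to 11–16 Hz and the RMS over 0.25 s windows
stepping 0.1 s is computed; events are maximal runs above the series' 95th
percentile over the scoring window. The percentile threshold ties the
detector's operating point to spindle *prevalence*: at 1–3 spindles/min of
~0.9 s each, sigma bursts occupy roughly 2–5% of the window, so the 95th
percentile sits just above the background. This makes the RMS detector
sensitive (it recovers >90% of true events on the synthetic world) but
imprecise when prevalence is low — exactly the failure mode the fusion stage
corrects.

Both detectors merge supra-threshold runs separated by < 0.2 s (spindle
envelopes often dip mid-burst) and keep only durations in [0.5, 3.0] s. Runs
longer than 3 s are discarded rather than truncated: sustained sigma power
over many seconds is more plausibly artifact (e.g. EMG leakage) than a
spindle.

## 2. Fusion

The fusion logic encodes one empirical observation and one corrective step:

1. **Agreement is trustworthy.** Events found by both detectors
   (transitively chained overlaps, resolved to the longest member — ties to
   the earlier onset, then wavelet before RMS) are accepted without further
   scrutiny.
2. **Disagreement is resolvable in feature space.** Detector-unique events
   are a mix of genuine spindles missed by one detector and false alarms.
   Their peak-to-peak amplitude and mean frequency are z-scored (sample SD;
   zero-SD dimensions map to 0) and clustered; clusters whose *labelled*
   members are strictly-majority non-spindle are dropped.

"Improved k-means" is realised as k-means++ seeding (deterministic given the
seed) with Lloyd iterations to a 1e-6 centroid-shift tolerance, and the
number of clusters selected by mean silhouette over k ∈ 2..6 (capped at
n − 1 and the number of distinct points; all-identical inputs give k = 1;
silhouette of singleton clusters is 0 by the usual convention; ties go to
the smaller k). The silhouette implementation is the package's own and is
pinned by a hand-computed three-point case in the tests.

**Where the labels come from.** The cluster-rejection step requires knowing,
for at least some unique events, whether they are spindles. In evaluation
runs the labels come from the expert consensus (true set and non-spindle
set); in simulations, from the generator's ledger. The two references differ
in an important way: the generator's ledger is *complete* — it knows every
true spindle — so a unique event matching nothing in it is labelled
`"false"`. The expert consensus is *partial* — experts only screened what
they noticed — so unmatched events stay `"unknown"` and do not vote.
Conflating the two (treating a partial reference as complete) would let
boundary disagreements between detector and experts masquerade as
non-spindles; treating a complete reference as partial disables the
rejection entirely (every unique-set false positive is unknown, no cluster
is ever majority-false). In fully unlabelled production runs the rejection
step is skipped with a warning, as the step is defined only relative to a
labelled reference. Clustering is per subject (channels pooled): amplitude
scales differ enough across subjects that pooling subjects would let one
subject's amplitude distribution dominate another's rejection decision; a
config flag allows pooling.

## 3. Evaluation

Consensus truth follows the two-of-three rule: two expert events match when
they overlap by at least 0.2 of the shorter event (the common
spindle-benchmark choice; the matching rule is config-exposed); any group
supported by ≥ 2 experts becomes one true event whose interval is the
*union* of the matched intervals. Union (rather than intersection) was
chosen so that boundary jitter between experts widens rather than shrinks
the truth — with jittered annotators an intersection systematically
under-covers the burst. Expert events supported by nobody form the
non-spindle set.

Recall, precision and F1 are event-level, by greedy one-to-one matching in
onset order (`tp + fn = |truth|`, `tp + fp = |pred|` are invariants under
test). Specificity and accuracy require true negatives, which have no
event-level definition, so they are computed on 0.5 s bins: a bin is
positive for a set when ≥ 50% of it is covered. Both granularities are
reported and labelled; they are not mixed. Per-metric across-subject
variances use the sample (n − 1) convention. All metrics are percentages;
zero-denominator metrics are reported as 0 and flagged rather than NaN.

## 4. The synthetic world

The generator is the package's substitute for a private clinical cohort and
is a *stated world*, not a tuning dial:

* 20 sleep-disordered (DS) and 10 normal (NS) subjects; 256 Hz; channels
  C3, C4, F3, F4; 20 min per subject in test runs (480 min emulates a full
  night — the statistical structure is identical, only event counts scale).
* Background: Gaussian $1/f$ noise at 15 µV RMS. Spindle bursts:
  Hann-windowed sinusoids; frequency a mixture with 70% of mass uniform on
  12–14 Hz and the rest uniform on the remaining sigma band; duration
  truncated-normal 0.9 ± 0.25 s on [0.5, 1.5]; peak-to-peak amplitude
  uniform 15–45 µV (DS) / 20–60 µV (NS).
* Densities are uniform per group over the published group extremes
  (DS 0.89–2.83 /min, NS 1.68–3.5 /min); onsets are Poisson with
  non-overlap enforced per channel; channels draw independently (so
  symmetric-channel count differences are small but nonzero, as in real
  recordings).
* PSQI scores: `round(clip(22 − 5.5·density + N(0, 1.2)))`, clipped to the
  group's score range (DS 11–21, NS 0–10). The intercept and slope are
  chosen so the two groups' density ranges map into their score ranges with
  realistic overlap pressure at the clip boundaries.
* Three simulated experts: detection probability logistic in amplitude,
  calibrated to 0.9 at the weakest generated amplitude and saturating above
  it (so per-event detection is ≥ 0.9 and the binomial two-of-three
  consensus recall exceeds 0.95); boundary jitter SD 0.05 s with the 0.5 s
  duration floor re-imposed; 0.2 false events per minute.

**The zero-coupling null.** The PSQI clip deliberately ties scores to group
membership, which is what a *coupled* world needs. But a type-I calibration
of the density–score correlation needs a world where scores are independent
of density yet still vary; zeroing the slope alone would leave the clip
acting as a group label and produce a spurious correlation through the
group-dependent density ranges (measured rejection rate 0.87 — not a type-I
error rate but a group effect). `null_coupling_params()` therefore defines
the null world explicitly: slope 0, intercept mid-scale (10.5), clip 0–21
for both groups. Under it the correlation test's rejection rate at
α = 0.05 is ≈ 0.07 over 200 seeds (computed by the acceptance script), and
the r distribution is centred at zero. Note that the expected *absolute*
correlation under an exact null at n = 30 is $\sqrt{2/(\pi \cdot 28)} \approx
0.148$ — small-sample |r| is not close to zero even when the null is true,
which is why the centring test bounds the *mean* of r, not mean |r|.

**What a green test does and does not establish.** The generator emulates
the statistical skeleton of annotated sleep EEG: power-law background,
band-limited waxing-waning bursts, group structure, imperfect annotators.
It does not emulate sleep microstructure (K-complexes, arousals, artifacts,
stage-dependent background changes), inter-channel correlation, or
non-stationary noise. Green detector tests therefore establish correctness
of the pipeline and sane behaviour at a realistic SNR operating point — not
clinical-grade performance on real polysomnograms, which would require
validation against a human-annotated benchmark.

## 5. Numerical choices

* **Filtering.** Zero-phase 4th-order Butterworth band-pass (8th order
  after forward–backward application), designed from the analog prototype
  via the low-pass→band-pass transform and the bilinear transform with
  frequency pre-warping. The filter is applied as a cascade of second-order
  sections rather than one expanded polynomial: the expanded order-8
  denominator has coefficients spanning 5 orders of magnitude and loses
  ~7 digits in recursion, while the biquad cascade keeps linearity error
  near 1e-14. Edge transients are absorbed by 3 s odd-reflection padding.
  Zero phase matters because event timestamps are read off the filtered
  trace and must align with the raw signal.
* **Timestamps** are real-valued seconds; conversion to sample indices
  rounds half away from zero at the consuming operation, so detectors
  operating at different step sizes remain comparable.
* **Intervals** are half-open `[onset, offset)`; touching events do not
  overlap, which makes downstream bin assignment unambiguous.
* **Mean frequency** uses a detrended, Hann-windowed periodogram
  zero-padded to 4 s (0.25 Hz resolution), power-weighted over 11–16 Hz;
  amplitude measures the sigma-filtered peak-to-peak within the event after
  padding the segment by 0.5 s context to absorb filter edge effects.
* **Histograms** use left-closed bins (frequency: five 1 Hz bands, the last
  closed at 16; amplitude: eight 10 µV bins, the last open-ended), so an
  event at exactly 13.0 Hz falls in [13, 14).
* **Rounding** of the first-cycle group means is commercial
  (half-away-from-zero) to 1 decimal, matching how such tables are printed;
  R's default half-to-even would turn 155.85 into 155.8.
* **EDF encoding** is 16-bit with per-channel symmetric physical scaling;
  the writer re-parses its own 7-significant-digit header fields so the
  round-trip error is bounded by the quantisation step (tested at
  range/2¹⁵).
* **Determinism.** Every stochastic routine takes an explicit seed and
  restores the caller's RNG state; regeneration of a cohort and a rerun of
  detect/evaluate are byte-identical (tested).

## 6. Known limitations and open points

* The printed first-cycle table's DS spindle-count average (156.3) is
  inconsistent with the mean of its own printed column (155.85); the
  package reports the computed mean (155.9 at 1 decimal) and leaves the
  discrepancy documented rather than patched.
* Whether detection should be restricted to N2 sleep (common practice) or
  run over the whole scoring window is left open; analyses default to the
  whole window and the hypnogram machinery supports stage masking.
* The published group-difference p-value is described both as a two-sample
  comparison and as a correlation; the package provides both (`welch_t`,
  `pearson`) and reports them side by side.
* Specificity/accuracy depend on the bin convention (width, coverage rule);
  the defaults (0.5 s, 50%) are declared in the config and reported with
  the metrics, but other conventions exist and change the numbers.
* The HMM–SVM comparison detector of the surrounding literature is out of
  scope; `compare_detectors()` covers wavelet-only, RMS-only and fusion.
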