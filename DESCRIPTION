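Package: spindlefusion
Title: Fusion Detection and Characterisation of Sleep Spindles in Polysomnographic EEG
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects sleep spindles (11-16 Hz, >= 0.5 s bursts of sigma-band
    activity) in multichannel sleep EEG by fusing a complex Morlet-wavelet
    envelope detector with a small-window RMS detector: detections found by
    both detectors are kept (longer event wins), while detector-unique events
    are clustered on peak-to-peak amplitude and mean frequency with a
    k-means++/silhouette procedure and clusters dominated by labelled
    non-spindles are discarded. Includes EDF and CSV readers/writers, hypnogram
    windowing (8 h scoring window, first sleep cycle), multi-expert consensus
    ground truth, event- and bin-level evaluation metrics with per-subject
    variance tables, spindle characteristics (density, amplitude, frequency,
    histograms, symmetric-channel counts), PSQI correlation analyses, and a
    deterministic synthetic annotated-PSG cohort generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
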