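Package: hrvstress
Title: Psychological Stress Classification from ECG Heart Rate Variability with Stacked GRU Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Pipeline for classifying four psychological stress states
    (resting, VR scene adaptation, VR task, recovery) from single- or
    multi-lead ECG. Filters the waveform, detects R waves, extracts seven
    heart-rate-variability features (mRR, SDNN, HFn, LFn, LF/HF, ApEn,
    SD1/SD2) over sliding 30-s windows, standardizes the resulting
    time-series samples with per-timestep min-max statistics learned on the
    training set, and classifies them with two cascaded stacked-GRU blocks
    feeding a fully connected softmax head, trained with Adam on a
    cross-entropy plus L2 loss. Includes an IPFM-based synthetic RR/ECG
    cohort generator so the full method can be trained and evaluated at
    desk scale, and cross-subject split/train/evaluate utilities with
    repeated-experiment averaging and confusion-matrix reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
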