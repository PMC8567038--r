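Package: adtfnet
Title: Time-Varying Directed EEG Networks via the Adaptive Directed Transfer Function
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how task conditions reshape directed cortical
    information flow in event-related EEG. Implements the full chain from raw
    multichannel epochs to time-varying effective-connectivity networks:
    standard ERP preprocessing (zero-phase band-pass filtering, epoch
    segmentation, baseline correction, amplitude-threshold artifact rejection,
    re-referencing, decimation), ERP component quantification with
    repeated-measures ANOVA (Greenhouse-Geisser corrected) and Wilcoxon
    signed-rank behavioural tests, and - centrally - Kalman-filtered
    time-varying multivariate adaptive autoregressive (tv-MVAAR) modelling with
    the Adaptive Directed Transfer Function (ADTF), band-integrated network
    construction, and substage source-node summaries. A synthetic-data module
    generates MVAR epochs with known ground-truth connectivity, ERP-like
    epochs, and behavioural response-time tables so every stage is testable
    against a recoverable target.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
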