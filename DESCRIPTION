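Package: infantemg
Title: Movement-Related Muscle Activity Analysis for Infant Surface EMG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and classification of muscle responses to passive joint
    movements and segmentation of spontaneous movement episodes in infant
    polymyographic recordings. Surface EMG channels are rectified and smoothed
    into RMS envelopes, a per-muscle baseline is estimated from quiet
    fragments, and supra-threshold bursts are detected, merged and classified
    as stretch responses (StR) or shortening reactions (ShR) relative to
    annotated flexion/extension phases, with latency, duration, amplitude and
    occurrence summaries. Movement units are segmented from 2D limb-endpoint
    trajectories by a velocity threshold with duration, merge-gap and
    excursion criteria, and within-unit antagonist-muscle correlation and
    coactivation indices are computed. A synthetic-data module generates EMG
    and kinematic sessions with complete ground truth so every stage of the
    pipeline can be validated by recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
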