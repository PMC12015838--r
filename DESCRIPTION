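Package: gazeproc
Title: Processing and Feature Extraction for Wearable Eye-Tracking Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Headless processing pipeline for wearable eye-tracker recordings
    exported as delimited text in the Pupil Cloud Neon dialect. Loads and
    validates the parallel gaze, fixation, blink, saccade, pupillometry and
    event streams together with a surface-mapping (area-of-interest)
    enrichment stream; epochs recordings by events; annotates every stream
    with binary region-of-interest membership; extracts a per-epoch battery
    of blink, fixation, gaze-movement, saccade and pupillometric indices;
    runs blink-based trial exclusion and two-sample comparisons; computes
    Welch periodograms and spectrograms of the pupil series; and prepares
    the standard visualisations (ROI-coloured pupil traces, blink rasters,
    saccade series, fixation density clouds, scan paths, histograms). A
    synthetic-recording generator with a ground-truth manifest makes the
    whole pipeline testable without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    MASS,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
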