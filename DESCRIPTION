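Package: afqc
Title: Quality-Controlled Atrial Fibrillation Screening from Single-Lead ECG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for rhythm-based atrial fibrillation (AF) screening from
    30-second single-lead handheld ECG recordings. Provides a seeded synthetic
    screening-corpus generator (sinus/AF/ectopic rhythms, transient noise
    artifacts), a reference QRS detector and event extractor, a small 1-D
    convolutional neural network that classifies each detector event as a true
    heartbeat or a false (noise) detection, a low-complexity RR-interval
    irregularity AF detector with event-level quality control, and evaluation
    utilities (event/recording/patient-level metrics, subject-level splits,
    constrained grid search over detector parameters).
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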