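Package: jfbench
Title: Jitter-Penalised F-Score Benchmarking of QRS Detectors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Stress-testing of QRS (heartbeat) detectors on electrocardiogram
    recordings. Implements the JF performance score, which combines the
    F1-score of beat detection with a penalty for residual temporal jitter
    after per-record median delay correction, alongside the classic
    fixed-tolerance-window sensitivity and positive predictivity. Ships
    reference real-time-capable detectors (Pan-Tompkins, EngZee, WQRS,
    Elgendi, matched filter), a seeded synthetic annotated-ECG generator
    with two lead morphologies and a five-step noise ladder emulating
    recording activities of increasing movement artefact, detection-stream
    corruption utilities for metric validation, and a benchmarking harness
    applying a one-sample t-test protocol against a 90% performance
    threshold.
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
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
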