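Package: emgmonitor
Title: EMG Activity Monitoring with Multi-Resolution Energy Operators
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects onset and offset change-points of muscle activity in
    single-channel surface electromyography (EMG). Implements the
    Teager-Kaiser energy operator, its lag-k generalization and the
    max-pooled multi-resolution variant (MTEO), median conditioning, a
    baseline double-threshold detector (MEOTD) and a fixed-weight
    network-style detector (MEONND), together with region-based
    onset/offset scoring, an Analytic Hierarchy Process (AHP) model for
    multi-criteria parameter tuning, and a labelled synthetic surface-EMG
    generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
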