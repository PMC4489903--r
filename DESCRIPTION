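Package: smfbmi
Title: Closed-Loop Decoding of Hand Movements from Slow Magnetic Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and decoding of magnetoencephalographic (MEG)
    recordings for closed-loop neuroprosthetic hand control. Implements
    the slow magnetic field (SMF) feature (500-ms window means z-scored
    against rest-period statistics), a radial-basis-function support
    vector machine movement-type decoder, a two-stage movement-onset
    decoder combining a Gaussian-process mutual-information estimator
    with an R_on/R_off movement detector, linear minimum-norm mapping of
    sensor features to cortical vertices with per-vertex ANOVA contrast
    maps, nested cross-validation and detection statistics, and a
    simulated closed-loop session driving a virtual prosthetic hand. A
    synthetic MEG generator with dipolar movement-related cortical
    fields makes the full pipeline testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    kernlab,
    methods,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
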