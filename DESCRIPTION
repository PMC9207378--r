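Package: fvlSAD
Title: Small Airway Disease Indices from Digitized Flow-Volume Loops
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Digitizes the expiratory limb of the flow-volume loop from
    rendered pulmonary function test report pages (perceptual-hash panel
    localization, tick-glyph axis calibration, intensity-threshold curve
    tracing) and quantifies late-expiratory flattening with three
    geometric indices: the angle at the 75-percent-of-vital-capacity
    point between the fitted early and late descent segments, the
    inclination of the late segment against the volume axis, and the
    log-ratio of the late-segment slope to peak expiratory flow. Includes
    cohort utilities (mean-minus-k-SD cutoffs, lower limit of normal,
    flattening classification, concordance rates, Fleiss' kappa), a
    synthetic report renderer with closed-form ground truth for
    end-to-end validation, and a batch pipeline with a run manifest.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    png,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
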