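Package: tetherclamp
Title: Analysis of AFM Force-Clamp and TIRF Recordings of
    Vesicle-Membrane Tethers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing combined atomic-force-microscope (AFM)
    force-clamp recordings and total-internal-reflection-fluorescence
    (TIRF) vesicle tracking of secretory-vesicle plasma-membrane tethers.
    Provides a seeded synthetic-recording generator with ground-truth
    event logs, cantilever calibration (deflection sensitivity, drift,
    pull-force conversion), semiautomatic detection of tether-extension
    force transients with exponential-decay fitting and two-line step
    estimation, event taxonomy (force-clamp, rapid and full-dissociation
    events; short, extended and complex classes), an evanescent-field
    model converting fluorescence intensity to vesicle height, a
    segment-selection cascade with audit trail, and summary statistics
    (exact binomial confidence intervals, Poisson rate comparisons,
    step-size histograms with Gaussian peak fits, and protein-unfolding
    extension arithmetic).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
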