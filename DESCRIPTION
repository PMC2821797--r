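Package: eegfwd
Title: EEG Forward Head Models and Cortical Point-Spread Resolution Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Comparative analysis of EEG forward (volume-conductor) head
    models on a cortex-like source space. Builds four-shell head geometries
    (scalp, skull, cerebrospinal fluid, brain) as concentric spheres or
    smoothly deformed realistic-like surfaces, computes lead fields with
    three solvers (sensor-fitted multilayer sphere series, linear-collocation
    boundary element method with isolated-skull correction, and a
    finite-difference volume conductor), and derives point spread function
    (PSF) maps, full-width-at-half-maximum resolution statistics, pairwise
    model comparisons, paired t-tests and PSF signal-to-noise summaries,
    including replication of published summary tables packaged as fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    minpack.lm,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
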