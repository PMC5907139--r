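Package: duspboolnet
Title: Boolean Modelling of DUSP Regulation Under Herceptin Treatment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for qualitative modelling of dual-specificity phosphatase
    (DUSP) regulation in HER2-positive breast cancer cells during the initial
    response to Herceptin. Provides a plain-text Boolean network dialect with
    synchronous and asynchronous simulation, attractor and limit-cycle
    detection, and qualitative pattern classification; a library of per-cluster
    DUSP/MAPK negative-feedback models with parameterizable inducer slots;
    delta-delta-Ct processing of qPCR threshold-cycle tables with dual
    reference genes; correlation-based hierarchical clustering of expression
    time courses; enumeration and ranking of candidate DUSP inducers by
    matching simulated dynamics to experimental patterns; and a synthetic
    qPCR data generator with planted cluster structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust
Config/testthat/edition: 3
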