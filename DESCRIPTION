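Package: irhic
Title: Hi-C Contact-Matrix Analysis of 3D-Genome Responses to Ionizing Radiation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of binned chromosome-conformation (Hi-C) contact
    matrices with a focus on quantifying changes after ionizing radiation:
    iterative matrix correction (ICE), fixed-total scaling, a
    Spearman-on-correlation reproducibility score, contact-frequency versus
    distance scaling curves with loess smoothing, A/B compartment
    eigenvectors, saddle-plot compartment strength, TAD boundary detection
    and strength scoring by insulation-score and Hicratio methods, aggregate
    pileups around boundaries and loop anchors, and paired signed-rank
    comparisons of boundary strength between conditions.  A synthetic
    contact-map generator plants known distance decay, compartments, TAD
    boundaries of controllable permeability, loops, bin biases and
    translocations so that every stage can be validated by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
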