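Package: thermosat
Title: Complexity and Coupling Analysis of Thermally Stimulated Skin
    Oxygen Saturation and Speed-Resolved Perfusion Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing skin oxygen-saturation and speed-resolved
    laser-Doppler perfusion recordings acquired under local thermal
    stimulation protocols. Implements multiscale entropy (MSE), multiscale
    fuzzy entropy (MFE) and the complexity area index (CAI) for
    oxygen-saturation signals, Spearman-correlation analyses coupling
    perfusion speed components (V1/V2/V3) to oxygen saturation both in the
    time domain and at the level of complexity indices, one-way group
    comparisons across stimulation temperatures with seeded permutation
    posttests, and a synthetic cohort generator that emulates combined
    diffuse-reflectance/laser-Doppler (EPOS-style) recordings with known
    ground truth so every analysis stage can be validated by simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
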