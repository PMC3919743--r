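Package: demict
Title: Dual-Energy Micro-CT Material Decomposition and Vascular Biomarkers
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for two-material (gold/iodine) dual-energy micro-CT
    analysis of tumor vasculature: sensitivity-matrix calibration from
    vials of known concentration, joint bilateral filtration of paired
    40/80 kVp volumes, per-voxel constrained two-material decomposition,
    gold-threshold tumor segmentation, and derived vascular biomarkers
    (fractional blood volume, intravascular subtraction, accumulated
    extravascular gold, blood half-life). Includes a synthetic digital
    mouse phantom that emulates the imaging physics and physiology of a
    longitudinal gold/iodine nanoparticle study, a minimal NIfTI-1 volume
    reader/writer, comparison statistics, and an end-to-end pipeline
    driver with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
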