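Package: conemosaiq
Title: Quantification of Cone Photoreceptor Mosaics and Reporter
    Double-Positive Cells
Version: 0.1.0
Authors@R:
    person("M.", "Keller", email = "mkeller@example.org",
           role = c("aut", "cre"))
Description: Tools for F0 CRISPR screens of photoreceptor identity in the
    zebrafish retina. Measures per-cell reporter fluorescence inside
    morphologically eroded label masks, calibrates double-positive
    classification thresholds from control distributions, summarizes
    photoreceptor densities per field, and compares groups with
    tie-corrected Kruskal-Wallis and Conover-Iman post hoc tests. An
    expression-matrix layer provides FPKM transformation, opsin-gene
    aggregation, differential-expression filter criteria, a
    transcription-factor expression criterion, and a rhodopsin-based
    rod-contamination score. A synthetic-data module generates retinal
    mosaic fields and negative-binomial expression matrices with known
    ground truth so the whole pipeline is testable without microscopy or
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
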