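Package: andkit
Title: Dual-Chromogen Histology Quantification and Circulating miRNA
    Biomarker Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies co-expression of a brown chromogen (DAB, marking a
    microRNA detected by in situ hybridization) and a red chromogen
    (FastRed, marking SSTR2 protein) on dual-stained brightfield histology
    fields at single-nucleus resolution. Provides rolling-ball illumination
    correction, optical-density colour deconvolution with the
    FastRed-FastBlue-DAB basis, fixed-threshold partition of tissue into
    three protein-expression zones, k-means nuclear detection with
    watershed splitting, per-nucleus marker classification, region
    statistics and rank correlation of marker positivity against
    expression zone. A companion module implements qPCR 2^-dCT fold
    enrichment, multiplicative predictor scores, empirical ROC curves with
    DeLong confidence intervals and Youden/Liu cut-off selection. A
    synthetic-fixture generator renders dual-stained scenes with known
    ground truth through the same Beer-Lambert stain-mixing model, so the
    whole pipeline is testable without patient material.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    tiff,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
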