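Package: drugsig
Title: Drug Efficacy Gene-Expression Signatures and Response Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives per-drug gene-expression signatures of drug efficacy from
    pharmacogenomic cell-line screens by resampling-based Spearman correlation
    feature selection, scores individual expression profiles against those
    signatures with rank-based single-sample methods (singscore and its
    stable-gene-anchored variant, stingscore), trains and cross-validates
    per-drug response prediction models (linear, quadratic and support-vector
    regression), classifies drugs into confidence tiers from cross-dataset
    Spearman correlation and concordance-index thresholds, and evaluates
    predictions against in-vivo tumor response via the normalized tumor
    response (NTR) statistic from xenograft growth curves. Includes a
    synthetic-data generator that plants sensitivity- and resistance-associated
    gene programs on a latent drug-sensitivity axis so the full pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    fgsea,
    jsonlite,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    survival
Config/testthat/edition: 3
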