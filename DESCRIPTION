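Package: drtme
Title: Dietary Restriction Signature Scoring in the Tumour Microenvironment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies dietary restriction (DR)-related molecular activity in
    bulk and single-cell expression data with a signed single-sample gene set
    enrichment (ssGSEA) score and a per-sample permutation test, and provides
    the downstream analyses that score feeds: arm/focal/chromosome copy-number
    burden scoring from segmented log2 ratios, panel-based immune cell and
    pathway scoring, the cytolytic activity (CYT) score, a two-gene
    hepatocellular carcinoma prognostic predictor, covariate-adjusted
    association models, survival contrasts (Kaplan-Meier, log-rank, Cox,
    landmark AUC with bootstrap confidence intervals), and synthetic-data
    generators with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    survival
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
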