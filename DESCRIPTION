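Package: eoclines
Title: Subtype Assignment and Tumor-Similarity Ranking for Ovarian Cancer Cell Lines
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assigns epithelial ovarian cancer (EOC) cell lines to histological
    subtypes by consensus clustering over multi-restart non-negative matrix
    factorization (NMF) with Kullback-Leibler multiplicative updates, selects the
    factorization rank from cophenetic-coefficient and permutation-null residual
    criteria, and ranks cell-line suitability as tumor models by Spearman
    correlation against subtype-stratified tumor expression. Includes the
    supporting preprocessing steps (variance stabilization, median-absolute-
    deviation gene filtering, upper-quartile normalization, parametric
    empirical-Bayes batch correction), a negative-binomial synthetic-panel
    generator with planted subtypes, batch effects and tumor-purity dilution for
    fully reproducible testing, and an end-to-end pipeline with provenance
    manifests and report figures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    sva,
    DESeq2
Config/testthat/edition: 3
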