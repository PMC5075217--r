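Package: amplicnv
Title: Germline Copy-Number Variant Detection in Multiplex-PCR Amplicon Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects germline copy-number variants (CNVs) at amplicon and
    exon resolution in targeted sequencing data enriched by multiplex PCR,
    where uneven amplification efficiency defeats library-size
    normalisation. Coverage anomalies are found by comparing each amplicon
    against groups of biochemically similar (coverage-correlated) amplicons:
    an unsupervised caller based on Sn-correlation partner selection,
    Theil-Sen robust regression and studentized-residual outlier voting, and
    a supervised classifier that fits per-amplicon copy-number models on a
    control set and combines chi-squared admissibility, normalised Euclidean
    distance with Benjamini-Hochberg FDR control, and Bayes-factor
    confirmation. Includes amplicon read counting from alignments,
    sample and amplicon quality control, and a multiplex-PCR coverage
    simulator with truth sets for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    Rsamtools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
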