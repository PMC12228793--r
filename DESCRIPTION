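Package: senatlas
Title: Senescence Atlas Analysis of Paired Single-Nucleus RNA and ATAC Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for single-nucleus multiome studies of cellular
    senescence in aging tissue. Provides unified senescence scoring and
    senescent-cell calling from rank-based single-sample gene-set enrichment,
    a depth- and composition-controlled transcriptional-noise statistic,
    rank-sum differential expression with SASP set algebra and hypergeometric
    over-representation, ligand-receptor communication probabilities with
    permutation significance and pathway information flow, pseudotime
    correlation and binned module-score curves, and paired RNA+ATAC regulatory
    inference (motif accessibility deviations, domains of regulatory chromatin,
    signed TF regulation scores, chromatin-lead dynamics, and peak
    annotation/target assignment). Includes a synthetic multiome generator
    with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
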