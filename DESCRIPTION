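Package: sigsim
Title: Expression Similarity Signatures Across Merged Tumor Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Extracts expression similarity signatures shared across merged
    bulk RNA-seq tumor cohorts. Implements the full analysis front end
    (counts-per-million and annotation filtering, upper-quartile
    normalization with gene-length correction, tumor-versus-normal log
    fold-change pre-filtering), principal-component-based unsupervised
    feature extraction with dual correlation thresholds, right-tailed
    Fisher (hypergeometric) gene-set enrichment against GMT collections,
    and capped interaction-network construction around signature genes
    ranked by hypergeometric scoring. Ships a negative-binomial
    multi-cohort count simulator with planted dysregulated genes and
    ground-truth labels so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    edgeR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
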