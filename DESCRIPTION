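Package: fuzzsig
Title: Integrative Gene-Signature Selection with a Mamdani Fuzzy-Rule Classifier
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selects robust tumor-versus-normal gene signatures by integrating
    gene expression with promoter CpG methylation: differentially expressed
    genes are intersected with differentially methylated genes (per-locus Welch
    t-tests, Fisher's combined probability test over promoter loci), and the
    final signature is chosen by an elastic-net classifier in which literature
    biomarkers receive reduced penalty factors. Classification uses a Mamdani
    fuzzy-rule model with three Gaussian linguistic terms induced from training
    samples by the Wang-Mendel construction. Includes a paired
    expression/methylation simulator with planted signal, stratified
    cross-validation with in-fold feature selection, quantile normalization for
    external cohorts, and side-by-side comparison of five feature-selection
    model variants.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    glmnet,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
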