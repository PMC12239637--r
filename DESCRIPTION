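Package: pollenTau
Title: Comparative Tissue-Specificity Analysis of Pollen, Style, and Leaf
    Expression with Pollen-Tube Phenotype Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for comparative analyses of tissue-specific gene
    expression between two Solanum species from bulk RNA-seq count
    matrices. Implements TPM normalization with subtissue and replicate
    averaging, the tau tissue-specificity index with tissue-biased and
    tissue-specific classification, cross-species expression-domain
    contrasts for pollen-biased genes, median-of-ratios size factors with
    per-gene species contrasts and Benjamini-Hochberg correction,
    keyword-based curation of pectin methylesterase (PME) and PME
    inhibitor (PMEI) gene families, and statistics for in vitro and in
    vivo pollen-tube growth assays. A negative-binomial synthetic-data
    generator with ground-truth labels supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
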