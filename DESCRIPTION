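Package: p53cc
Title: Cross-Cancer Analysis of TP53 Mutation Effects on p53 Pathway Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for pan-cancer analysis of how TP53 mutations
    (and their gain-of-function and non-gain-of-function subtypes) alter the
    expression of p53-signaling-pathway genes. Provides transactivation-informed
    variant classification and per-sample TP53 genotyping from MAF-like tables,
    FPKM-to-TPM conversion with a low-expression gene filter, log2
    median-ratio matrices per cancer type, unsupervised hierarchical clustering
    of cancer types with Pearson correlation distance and complete linkage,
    exact and normal-approximation Wilcoxon rank-sum tests, Fisher exact tests,
    discriminant-gene extraction with pathway-category tallies, and a
    TCGA-shaped synthetic data generator with planted cluster structure so the
    whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
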