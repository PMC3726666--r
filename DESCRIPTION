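Package: sagescope
Title: SAGE Tag Counting, Differential Expression and qPCR Validation for
    Single-Library Transcriptome Comparisons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for serial analysis of gene expression (SAGE)
    sequencing data: builds a virtual NlaIII (CATG-anchored) tag database
    from a reference transcriptome, assigns observed tags to genes with a
    bounded-mismatch ambiguity-rejecting matcher, normalizes counts to tags
    per million (TPM), calls differentially expressed genes between two
    unreplicated libraries by fold change with a one-tag pseudo-count for
    zeros, tests gene-set over-representation with fold enrichment and an
    exact hypergeometric p-value, and validates candidate biomarkers from
    RT-qPCR cycle-threshold tables via geNorm reference-gene stability,
    geometric-mean normalization and minus-delta-delta-Ct fold changes,
    including hierarchical clustering of fold-change panels. A simulation
    module generates transcriptomes, tag libraries with sequencing errors,
    gene sets with planted enrichment and Ct tables with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    ape,
    fgsea,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
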