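Package: methregen
Title: Tissue-Culture-Induced DNA Methylation Change Analysis for Plant Methylomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Calls differentially methylated regions (DMRs) from per-cytosine
    bisulfite-sequencing counts using Fisher's exact test on 100-bp bins with
    Benjamini-Hochberg FDR control, per-context absolute-difference thresholds
    and an informative-cytosine filter; compares DMR sets across samples and
    generations (asymmetric overlap matrices, common DMRs, hierarchical
    clustering of methylation matrices, transgenerational stability
    classification); tests genomic-feature enrichment against randomized
    interval sets; integrates promoter hypomethylation with mRNA expression
    (RPKM, fourfold/FDR differential calls) and 24-nt siRNA coverage; and
    ships a synthetic-methylome generator with a truth ledger for end-to-end
    recovery testing. All user-facing functions take and return tidy data
    frames.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    Rcpp,
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    jsonlite,
    withr
Config/testthat/edition: 3
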