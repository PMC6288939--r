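Package: delandscape
Title: Exon-Level Differential Expression and the Landscape of Sex-Biased
    Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An exon-level RNA-seq differential-expression pipeline for
    2x2 sex-by-treatment designs. Flattens a GFF3 annotation into unique
    exonic regions (excluding regions ambiguous between genes), applies an
    average-per-nucleotide-coverage detection filter, computes ln-RPKM
    expression, tests the four pairwise sex/treatment contrasts with
    Welch-Satterthwaite statistics robust to variance heterogeneity,
    rolls exon calls up to genes, classifies the sex-differential
    expression landscape (maintained, gained, lost, reversed bias), and
    performs hypergeometric gene-set enrichment against an
    annotation-restricted background. A negative-binomial simulator with
    planted effect structure makes every stage testable without external
    reads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    stringr,
    withr,
    yaml,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
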