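Package: troutmir
Title: Hepatic Small RNA-Seq miRNA Discovery, Annotation and Target Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end, testable re-implementation of a hepatic small
    RNA-seq analysis workflow for salmonid fish: adapter trimming and read
    accounting, collapsing of reads into unique tags, miRBase-style mature
    miRNA matching, genome placement, single-stem-loop hairpin folding with
    an 11-criterion structural filter, the gp1a-gp4b annotation decision
    tree, median-of-ratios normalization with two-group differential
    expression, miRanda-style 3'UTR target prediction with duplex free
    energy, GO term over-representation, and the companion qPCR validation
    statistics (standard-curve efficiency, NORMA-Gene normalization, Grubbs
    outlier test, Welch and ANOVA/Tukey comparisons, Pearson correlation).
    A synthetic-data module generates references, reads and ground truth so
    the whole pipeline runs with no external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    DESeq2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
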