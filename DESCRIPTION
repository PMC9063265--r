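Package: trnaquant
Title: Mature tRNA Quantification and Differential Expression from Small RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies mature transfer RNA (tRNA) expression from single-end
    small RNA sequencing data. Builds an artificial genome in which annotated
    tRNA genes are masked and re-appended as premature decoy chromosomes
    (gene body plus 50 nt flanks), and a mature tRNA reference with introns
    spliced and the 3' CCA tail appended. Reads are mapped with a native
    ungapped up-to-k-mismatch best-hit aligner, classified as non-tRNA,
    premature or mature, and re-mapped to the mature reference for counting at
    three aggregation levels (individual tRNA, isodecoder, isoacceptor).
    Downstream analysis provides CPM prevalence filtering, TMM normalization,
    a common-dispersion negative-binomial exact test for two-group comparisons
    with Bonferroni and Benjamini-Hochberg correction, and plot-ready tables
    for MDS, volcano, anticodon bar and amino-acid pyramid displays. A
    synthetic-data generator with known ground truth supports validation of
    every stage.
License: GPL-3
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    ggplot2,
    jsonlite,
    methods,
    rlang,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    cluster,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
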