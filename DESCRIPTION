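Package: methylbin
Title: Binomial Methylation Calling and Binned Differential Methylation
    Analysis for Plant Whole-Genome Bisulfite Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing whole-genome bisulfite sequencing methylomes
    in plants, in the three cytosine contexts CG, CHG and CHH. Implements
    methylcytosine calling by an exact one-sided binomial test against the
    bisulfite non-conversion rate, differentially methylated cytosine and
    region detection (Fisher's exact test in 100-bp bins with an
    informative-cytosine filter and Benjamini-Hochberg FDR control),
    metagene and RdDM-locus methylation profiles, sliding-window chromosome
    tracks, transposable-element length-class summaries, and integration of
    promoter methylation with gene expression (correlation, k-means
    expression clustering, differential-expression filtering, siRNA-overlap
    gene grouping). A seeded synthetic-data generator produces miniature
    genomes, bisulfite count reports with planted differentially methylated
    regions, 24-nt siRNA loci and coupled expression tables together with
    ground-truth tables, so every stage of the pipeline can be exercised and
    benchmarked at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    withr,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    mclust
Config/testthat/edition: 3
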