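Package: episigr
Title: Integrative Epigenome Clustering by Alignment-Aware Seeded Sampling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clusters genomic regions by their joint multi-mark epigenomic
    profiles. Fixed-width genome windows carrying enriched signal in any
    assay (histone ChIP-seq, ATAC-seq, RNA-seq coverage, whole-genome
    bisulfite methylation) are sigmoid-normalized, concatenated across
    samples and marks into one data window per region, and grouped by an
    iterative procedure: an entropy-based seed is chosen, then remaining
    regions are accepted or rejected by a Gibbs-sampling-like rule while
    being shifted and orientation-flipped to align their patterns. Clusters
    are summarized into sections with a self-organizing map, tested for
    enrichment of differentially modified regions between two sample groups
    with exact hypergeometric tests, and annotated against genomic features
    with regulatory-domain gene assignment. A synthetic-landscape generator
    with planted archetypes, shifts, flips and group effects provides ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    dplyr,
    generics,
    GenomicRanges,
    GenomeInfoDb,
    ggplot2,
    IRanges,
    purrr,
    Rcpp,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    jsonlite,
    knitr,
    mclust,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
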