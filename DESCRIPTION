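Package: multiOverlap
Title: Enrichment of n-Wise Overlap Combinations Between Genomic Region Sets
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes the statistical enrichment of n-wise (n >= 2) overlap
    combinations between sets of genomic regions. Observed overlaps are found
    with a sweep-line algorithm over BED-style interval sets; a Monte Carlo
    null model shuffles each set by permuting its region lengths and
    inter-region gap lengths, and a Negative Binomial distribution is fitted
    by the method of moments to the shuffled overlap statistics to obtain
    resolutive upper-tail p-values, with empirical and Beta-distribution
    p-values as companions and a Cramer's V goodness-of-fit diagnostic.
    An optional itemset miner based on sparse dictionary learning pre-selects
    noise-robust combinations of interest from the binary overlap matrix.
    Results are exported as TSV tables and as a parent/child combination
    graph in DOT format.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
biocViews: GenomeAnnotation, StatisticalMethod, Epigenetics, Transcription
Config/testthat/edition: 3
RoxygenNote: 7.3.3
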