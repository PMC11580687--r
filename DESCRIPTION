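Package: slrscan
Title: Detection of Sex-Linked Regions and Sex-Chromosome Turnovers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for locating sex-linked regions (SLRs) on the sex
    chromosomes of dioecious diploids and for characterising
    sex-chromosome turnovers. Implements the chromosome quotient (CQ)
    statistic on windowed female/male read coverage, the Weir-Cockerham
    between-sex FST estimator in overlapping windows, PELT changepoint
    segmentation of the FST profile with SLR boundary calling, genotype
    r2 linkage-disequilibrium summaries and decay curves, gametolog
    gene-tree topology classification (gametolog clustering, species
    clustering, neo-Y-from-X), gene gain/loss and duplicate-integrity
    rules for Y-linked candidate genes, and a Fisher exact test of the
    association between chromosomal inversions and sex linkage. A
    synthetic-data generator produces genotype, coverage, sequence and
    comparison-table inputs with known truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    vcfR,
    rtracklayer,
    IRanges,
    GenomicRanges,
    S4Vectors,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
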