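Package: pedgen
Title: Kinship, Inbreeding and Relatedness-Informative Marker Panels for
    Managed Populations
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pedigree-aware population genomics for managed and semi-captive
    animal populations genotyped at biallelic SNPs. Implements the KING-robust
    pairwise kinship estimator with relatedness-degree classification, greedy
    selection of an unrelated sample subset, inference of unrecorded
    father-offspring pairs from kinship and age records, exact detection of
    runs of homozygosity under five explicit criteria with the genomic
    inbreeding coefficient F_ROH, a multi-class homozygosity-by-descent hidden
    Markov model that partitions each genome into age-resolved autozygosity
    classes, and construction plus resampling-based validation of reduced
    relatedness-informative marker (RIM) panels. A pedigree-genotype simulator
    with recombination, reproductive skew and matrilineal-only pedigree
    visibility supports end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    vcfR,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
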