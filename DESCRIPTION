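Package: emsco
Title: Crossover Detection and Recombination Landscapes from EMS-Induced
    Markers
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects meiotic crossovers (COs) genome-wide in Arabidopsis-style
    crossing designs. For inbred lines carrying sparse heterozygous
    EMS-induced mutation markers, markers are phased by a sliding-window
    hierarchical-clustering method with voting-based genotype imputation, and
    COs are called as consistent phase switches with read-level border
    refinement and chromosome-terminus validation. For hybrid backcross/F2
    progeny genotyped at dense SNPs, COs are called by sliding-window
    genotyping with an allelic-ratio homozygosity threshold and per-SNP
    breakpoint refinement. The package also builds megabase-scale
    recombination-landscape tracks (windowed CO frequencies with bootstrap
    confidence bands, per-chromosome normalization, moving-average smoothing
    and z-scoring), detects peaks and valleys, compares tracks by rank and
    segmented non-linear correlation, runs permutation overlap tests of COs
    against genomic region sets, and summarises crossover interference via
    the coefficient of coincidence. A forward simulator of the crossing
    designs (gamma-renewal meiosis with interference, obligate-CO option,
    heterozygous-inversion suppression, low-coverage read sampling) provides
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    Matrix,
    data.table
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation,
    rtracklayer,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Genetics, SNP, Sequencing, Software
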