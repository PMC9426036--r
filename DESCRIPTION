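Package: wgdclock
Title: Genome Doubling Detection, Haploidisation Calling and
    Molecular-Clock Timing from Allele-Specific Copy Number
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying tumour genome evolution from
    allele-specific copy-number segments and somatic SNV calls:
    classification of copy states (diploid, gain, copy-neutral LOH,
    other), detection of whole-genome doubling by mixture-model
    clustering of major-allele ploidy, calling of partial
    haploidisation from the LOH genome fraction, molecular-clock timing
    of genome doubling from SNV multiplicities, hotspot driver
    genotyping (IDH1/IDH2/TERT), and cohort-level exact contingency and
    rank-sum statistics with arm-level gain/loss comparisons and a
    chromosome fragmentation statistic.  Includes a synthetic tumour
    generator with known haploidisation and doubling history so that
    every inference stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
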