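Package: LADid
Title: DamID-Seq Processing and Lamina-Associated Domain Calling
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Processing of DamID-seq experiments from aligned reads to
    lamina-associated domain (LAD) calls. Implements in-silico GATC/DpnI
    fragmentation of a reference genome (or fixed-size binning), alignment
    filtering with mitochondrial-contamination accounting, per-fragment
    log2(LaminB1-Dam / Dam-only) ratio profiles with quantile normalization
    and fragment-window smoothing, circular binary segmentation with a
    permutation significance test, and rule-based LAD calling (gap
    subtraction, thresholding, merging, minimum-size filtering). A DamID
    experiment simulator with known ground truth supports end-to-end
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    Rsamtools,
    rtracklayer,
    limma,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: Epigenetics, Sequencing, Software, Coverage, PeakDetection
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'LADid-package.R'
    'RcppExports.R'
    'digest.R'
    'io.R'
    'lads.R'
    'segmentation.R'
    'profile.R'
    'qc.R'
    'pipeline.R'
    'simulate.R'
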