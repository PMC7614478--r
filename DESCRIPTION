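Package: morphoevo
Title: Multi-Region Tumour Morphology and Clonal Evolution Analysis
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of multi-region lung adenocarcinoma cohorts relating
    histological growth patterns to clonal evolution. From per-region
    allele-specific copy-number segments, mutation clusters with cancer cell
    fractions, and clone trees, the package classifies somatic copy-number
    alteration states and their clonality (truncal/subclonal arm and focal
    events, mirrored subclonal allelic imbalance), computes intra-tumour
    heterogeneity metrics (wGII, FLOH, percent subclonal SCNA and TMB,
    subclonal diversity, recent subclonal expansion), builds cytoband-level
    loss-of-heterozygosity and mutation matrices with inter-region Euclidean
    distances, infers ancestor-like/descendant-like regional pairs from LOH
    trees with Monte-Carlo permutation tests for grade-transition direction,
    and provides a ground-truthed synthetic cohort generator so every stage
    is testable without patient data.
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
    nlme,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
biocViews: CopyNumberVariation, SomaticMutation, Software
RoxygenNote: 7.3.3
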