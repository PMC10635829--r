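Package: medtrace
Title: Temporal Gene-Activity Tracing from Methylation-Label Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for methylation-dependent restriction-enzyme
    sequencing (MeD-seq) experiments in which a bacterial DCM
    methyltransferase fused to RNA polymerase II deposits CCWGG methylation
    on transcribed gene bodies and active enhancers, turning past
    transcriptional activity into a heritable, sequencable label.  The
    package scans references for DCM (CCWGG) and LpnPI CpG-context sites,
    filters and classifies 32-bp reads by restriction-site offset, builds
    normalized per-site count matrices, calls significantly labeled genes
    and intergenic enhancer DMRs with rank tests, assigns temporal peak
    days, estimates per-division label-propagation rates from H2B-GFP
    pulse-chase data, runs in-silico label-dilution experiments, and
    quantifies co-methylation linkage of neighbouring sites within reads.
    A fully parameterised synthetic-data generator produces toy genomes,
    ground-truth time courses, and MeD-seq-style reads for recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
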