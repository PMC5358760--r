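Package: pol3roadblock
Title: Detection of RNA Polymerase III Transcription Units Nested in Pol II
    Genes and of the Pol II Elongation Roadblocks They Create
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to locate RNA polymerase III (Pol III) transcription units
    (tRNA genes, SINEs such as MIRs) nested inside Pol II transcription units
    from ChIP-seq data, and to detect the localized Pol II accumulations
    ("roadblocks") that active Pol III units create in the path of the
    elongating Pol II. Implements multiplicity- and multi-mapping-aware tag
    weighting (uniform c/m split and an EM reallocation guided by uniquely
    mapping tags) so that repetitive Pol III loci are quantified correctly,
    log2(IP/input) occupancy scoring with percentage normalization and class
    means, a peak-confirmation and nesting funnel with NELF/DSIF-based
    classification of intragenic Pol II accumulations, a type-2 Pol III
    internal promoter (A-box/B-box) scanner, percent-identity neighbor-joining
    trees of element copies, and a fully seeded synthetic-data generator
    (genomes with near-identical repeat families, gene models with TSS pausing
    peaks, planted Pol III units and roadblock pileups) so every stage is
    testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    phangorn,
    Rsamtools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
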