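Package: chicsv
Title: Capture Hi-C Contact Maps, Subtraction Maps and Virtual 4C at
    Structural-Variant Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Locus-scale capture Hi-C analysis of structural variants:
    binning of fragment-resolved contact pairs into symmetric matrices,
    Knight-Ruiz-style matrix balancing and copy-number-aware iterative
    correction (LOIC), distance-decay-matched subtraction maps with
    breakpoint-region exclusion, and virtual 4C viewpoint profiles with
    windowed integrated-signal quantification and replicate merging.
    Includes a synthetic contact-data engine that models a two-TAD locus
    with CTCF loops and restriction-fragment granularity, simulates
    tandem duplications, inversions and knock-in insertions through an
    explicit segment-map algebra, and projects rearranged-genome contacts
    back to reference coordinates to emulate reference-only read mapping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    BiocGenerics,
    Biostrings,
    data.table,
    GenomicRanges,
    grDevices,
    graphics,
    IRanges,
    jsonlite,
    methods,
    rtracklayer,
    S4Vectors,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
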