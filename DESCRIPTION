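Package: oceanc
Title: Hubs of Open Chromatin Interactions from Hi-C-Style Read Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of open-chromatin enrichment Hi-C (OCEAN-C style)
    experiments. Classifies aligned read pairs into valid and artifact classes
    (dangling end, self-circle, same-strand, too-close), calls hubs of open
    chromatin interactions (HOCIs) from valid-pair end coverage with a Poisson
    local-background test, annotates hubs as promoter or enhancer elements from
    histone-modification peaks, builds the hub-hub interaction network, types
    genes as hub, interacting or dissociative and relates types to expression,
    identifies super-enhancers (stitching plus slope-1 tangent cutoff) and broad
    H3K4me3 domains, and computes ICE-balanced contact matrices with A/B
    compartments and insulation-score boundaries. Includes a synthetic-data
    generator with planted ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
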