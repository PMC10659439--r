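Package: rdgraph
Title: Ribosome Decision Graphs for Modelling mRNA Translation Complexity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Represents eukaryotic mRNA translation as ribosome paths through
    translated regions (translons) with probabilistic branching points:
    initiation by leaky scanning, re-initiation after short upstream open
    reading frames, stop-codon readthrough and selenocysteine insertion, and
    programmed ribosomal frameshifting. Builds a directed acyclic Ribosome
    Decision Graph (RDG) per transcript from a compact branch-point notation,
    enumerates ribosome paths and their proteoform products, analyses the
    impact of transcript variants on graph topology, quantifies branch
    probabilities from ribosome-profiling footprint densities, and simulates
    footprint tracks from known branch probabilities.
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
    rtracklayer,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    igraph,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
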