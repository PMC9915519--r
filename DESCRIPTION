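Package: omnitigs
Title: Simple Omnitigs and Safe-Walk Analysis for Genome Assembly Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for working with assembly graphs built from error-free
    k-spectra: construction of arc-centric de Bruijn graphs, enumeration of
    maximal unitigs and maximal simple omnitigs (univocal extensions of
    unitig cores), conversion of bidirected GFA graphs to doubled plain
    graphs, verification of safety guarantees for linear multi-chromosome
    and circular genomes, seeded synthetic genome and graph generators with
    planted repeats and bubbles, and alignment-based contiguity evaluation
    via the EAxmax metric family with homopolymer compression and unique
    misassembly merging.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
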