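Package: pflutype
Title: PCR-Marker Phylogroup Typing for the Pseudomonas fluorescens Complex
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies isolates of the Pseudomonas fluorescens species
    complex into its eight phylogroups from a nine-marker presence/absence
    PCR panel. Implements in-silico PCR with degenerate (IUPAC) primers
    under total and 3'-window mismatch budgets, the marker-by-phylogroup
    decision matrix with a two-positive-reaction rule, deconvolution of
    pooled environmental samples into compatible phylogroup sets,
    group-specific marker discovery from pan-genome orthology tables with a
    sequence-level similarity re-screen, conserved-block degenerate primer
    design with melting-temperature and dimer/hairpin quality checks, and
    seeded synthetic-fixture generators (marker templates, phylogroup
    genomes, communities, pan-genomes) so the whole pipeline is testable
    without downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    optparse,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
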