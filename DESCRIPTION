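Package: pondlife
Title: Agent-Based Simulation of Protocell Evolution by Vesicle Merger
    in a Wet-Dry Cycling Pond
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Stochastic agent-based simulator of protocell evolution in a
    "warm little pond" subject to alternating wet and dry phases.  Vesicles
    carrying peptide and RNA inventories collide, merge and acquire one
    another, join biopolymers, absorb monomers, and progressively assign
    amino acids to codon sets; the simulator tracks the emergence of FUCAs
    (first universal cellular ancestors) and of a LUCA carrying a complete
    twenty amino-acid genetic code.  Provides the four experiment designs
    (first stage, second stage, combined, and a merging-disabled control),
    replicate batches with per-cycle census tables, and deterministic
    seeded runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
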