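Package: bcescan
Title: Detection, Classification and Conservation Profiling of Bce-Like
    Antibiotic Resistance Modules in Bacterial Genomes
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Screens bacterial proteomes and gene maps for Bce-like modules:
    two-component signal transduction systems (response regulator plus
    intramembrane-sensing histidine kinase) paired with ABC transporters
    whose translocator carries an unusually large extracytoplasmic loop.
    Provides membrane-topology parsing and architecture filtering of kinase
    and translocator candidates, seed-based component calling by local
    alignment or imported BLAST tabular evidence, chromosomal clustering of
    component genes with composition classification, reference-anchored
    subfamily assignment on phylogenetic trees with cross-component
    concordance, per-region alignment conservation profiling, and a seeded
    synthetic-data generator with known truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    phangorn,
    Biostrings,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
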