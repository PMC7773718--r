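Package: minibar
Title: Plastome Mini-Barcode Design and Amplicon Metabarcoding
    Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mining hypervariable protein-coding regions from
    pairs of annotated organelle genomes, designing short taxon-specific
    barcode ("mini-barcode") primer pairs under physicochemical
    constraints (nearest-neighbor melting temperature, GC content,
    hairpin and primer-dimer screens), validating candidates by
    mismatch-tolerant in-silico PCR, and quantifying closely related
    species in processed mixtures from dual-tagged paired-end amplicon
    reads via exact sequence variant (ASV) dereplication, abundance-based
    denoising, reference assignment and read-proportion regression.
    Includes seeded simulators for diverged genome pairs and tagged
    amplicon mixtures with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
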