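Package: satmine
Title: Satellitome Mining and Quantification from Low-Pass Shotgun Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Iterative discovery of satellite DNA (satDNA) families from
    unassembled low-pass paired-end shotgun reads, with similarity-tier
    classification of monomers into variants, families and superfamilies,
    abundance estimation by read masking, Kimura-2-parameter repeat
    landscapes, catalog nomenclature and summary statistics, and
    cross-library screening including female-versus-male abundance ratios
    for detecting W-linked satellites in ZW species. Includes a seeded
    synthetic-data generator that plants tandem-repeat families of known
    monomer, abundance and divergence into diploid genomes and emulates
    low-pass paired-end sequencing, so every stage of the pipeline can be
    validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
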