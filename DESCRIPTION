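Package: primerworks
Title: Batch PCR Primer Design, Thermodynamic Screening and Primer Maps
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Window-constrained PCR primer discovery from multi-record DNA
    FASTA files and dbSNP-style SNP flanking sequences, with
    nearest-neighbor melting-temperature models (Breslauer and SantaLucia
    parameter sets, Schildkraut and Owczarzy salt corrections),
    self-complementarity, cross-dimer and hairpin screening, repeat and GC
    clamp rules, mismatch-tolerant specificity checks against the whole
    input set, allele-specific SNP genotyping primer design, all-pairs
    primer-dimer compatibility reports, and scalable SVG primer maps
    (per-sequence and concatenated). Includes a seeded simulator for both
    input kinds and a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
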