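Package: cpbarcode
Title: Whole-Chloroplast Barcoding from Shotgun Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds whole-chloroplast genome barcodes from shotgun sequencing
    reads and reconciles them across sequencing platforms. Provides a
    platform-aware read simulator (substitution-dominated paired short reads
    and homopolymer-indel-dominated single reads), quality trimming, a
    seed-and-extend read mapper with majority-vote consensus extraction, a
    de Bruijn assembler with contig-to-reference scaffolding, variant
    extraction and classification (SNP/MNV/insertion/deletion, with
    homopolymer context and indel bias summaries), and an evidence-based
    procedure that resolves cross-platform discrepancies into an amended
    consensus barcode validated by remapping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
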