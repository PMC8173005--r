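Package: panenrich
Title: Focused Phage-Display Library Models and Biopanning Enrichment Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytics for focused (secondary) phage-display peptide libraries
    screened by single-round biopanning and deep sequencing. Provides exact
    amino-acid frequency expectations for hard (NNK) and soft (doped)
    degenerate codon schemes under configurable amber-suppression policies,
    theoretical diversity and stop-codon burden calculations, a synthetic
    single-round screen simulator (naive library plus replicate eluates with
    selection weights and nonspecific background), flank-anchored insert
    extraction and translation from FASTQ reads, and per-position residue and
    per-peptide enrichment-factor computation with replicate-concordance hit
    ranking and consensus derivation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
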