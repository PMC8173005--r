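# Shared fixtures: schemes, codons, and an independent brute-force oracle
# for codon amino-acid distributions.

soft_codon <- function() {
  parse_degenerate_codon(list(c(10, 10, 70, 10),
                              c(70, 10, 10, 10),
                              c(10, 10, 10, 70)))
}

# Three-position scheme (fixed Gly, NNK, Tyr/Phe) with short but valid
# flanks; 40-residue peptide space under amber-to-Gln.
tiny_scheme <- function() {
  library_scheme(
    positions = list(position_fixed("G", "GGT"),
                     position_randomized("NNK"),
                     position_randomized("TWT")),
    flank5 = "AATTCCATGGCC",
    flank3 = "GCGGCCGCCTAA")
}

# Two hard-randomized positions: 400 stop-free peptides.
pair_scheme <- function() {
  library_scheme(
    positions = list(position_randomized("NNK"),
                     position_randomized("NNK")),
    flank5 = "AATTCCATGGCC",
    flank3 = "GCGGCCGCCTAA")
}

all_fixed_scheme <- function() {
  library_scheme(
    positions = list(position_fixed("G", "GGT"),
                     position_fixed("W", "TGG"),
                     position_fixed("F", "TTT")),
    flank5 = "AATTCCATGGCC",
    flank3 = "GCGGCCGCCTAA")
}

# Independent oracle: enumerate all 64 codons explicitly and accumulate
# products of the codon's marginal nucleotide probabilities by translated
# residue (standard genetic code via Biostrings).
oracle_aa_dist <- function(codon, amber_to_gln = TRUE) {
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(b1 = bases, b2 = bases, b3 = bases,
                      stringsAsFactors = FALSE)
  cods <- paste0(grid$b1, grid$b2, grid$b3)
  pr <- codon$p1[grid$b1] * codon$p2[grid$b2] * codon$p3[grid$b3]
  aa <- unname(Biostrings::GENETIC_CODE[cods])
  if (amber_to_gln) aa[cods == "TAG"] <- "Q"
  tapply(pr, aa, sum)
}

# Multinomial read counts drawn directly from closed-form frequencies,
# bypassing read generation (for estimator-level properties).
counts_from_freqs <- function(peptides, freqs, depth, sample = "s") {
  k <- as.integer(stats::rmultinom(1, depth, freqs))
  peptide_count_table(stats::setNames(k, peptides)[k > 0], sample = sample)
}
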