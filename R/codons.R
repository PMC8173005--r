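.BASES <- c("A", "C", "G", "T")

# IUPAC degenerate-base alphabet: each letter names the set of bases it allows.
.IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

# Amino-acid symbol order used throughout: the 20 standard residues then '*'.
.AA_LEVELS <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "*"
)

.STOP_CODONS <- c("TAA", "TAG", "TGA")
.AMBER <- "TAG"

# All 64 codons, lexicographic in A < C < G < T.
.ALL_CODONS <- as.vector(t(outer(
  as.vector(t(outer(.BASES, .BASES, paste0))), .BASES, paste0
)))

.norm_ratio <- function(v, pos) {
  if (length(v) != 4L || !is.numeric(v) || any(!is.finite(v)) || any(v < 0)) {
    stop("nucleotide ratio vector at codon position ", pos,
         " must be 4 finite nonnegative numbers (A, C, G, T)", call. = FALSE)
  }
  s <- sum(v)
  if (s <= 0) {
    stop("all-zero nucleotide ratio vector at codon position ", pos,
         call. = FALSE)
  }
  p <- as.numeric(v) / s
  names(p) <- .BASES
  p
}

#' Build a degenerate codon from an IUPAC triplet or explicit nucleotide ratios
#'
#' A degenerate codon is described by three probability vectors over the
#' nucleotides A, C, G, T -- one per codon position. An IUPAC triplet such as
#' `"NNK"` places uniform probability on the bases each letter allows
#' (N = any base, K = G or T, W = A or T, ...). Explicit ratios describe
#' soft randomization (doping), e.g. a codon synthesized from a
#' 70/10/10/10 nucleotide mix at each position.
#'
#' @param code Either a 3-letter IUPAC string (e.g. `"NNK"`, `"TWT"`,
#'   `"TGG"`), or a list of three numeric vectors of length 4 giving relative
#'   amounts of A, C, G, T at codon positions 1-3 (normalized internally).
#' @return A `degenerate_codon`: a list with components `p1`, `p2`, `p3`,
#'   each a named probability vector over `c("A","C","G","T")` summing to 1.
#' @examples
#' parse_degenerate_codon("NNK")
#' parse_degenerate_codon(list(c(10, 10, 70, 10), c(70, 10, 10, 10), c(10, 10, 10, 70)))
#' @export
parse_degenerate_codon <- function(code) {
  if (is.character(code)) {
    if (length(code) != 1L || nchar(code) != 3L) {
      stop("IUPAC codon code must be a single 3-letter string", call. = FALSE)
    }
    letters3 <- strsplit(toupper(code), "")[[1]]
    ps <- lapply(seq_len(3L), function(i) {
      allowed <- .IUPAC[[letters3[i]]]
      if (is.null(allowed)) {
        stop("unknown IUPAC letter '", letters3[i], "' in codon code '",
             code, "'", call. = FALSE)
      }
      p <- stats::setNames(numeric(4L), .BASES)
      p[allowed] <- 1 / length(allowed)
      p
    })
  } else if (is.list(code) && length(code) == 3L) {
    ps <- lapply(seq_len(3L), function(i) .norm_ratio(code[[i]], i))
  } else {
    stop("code must be an IUPAC triplet string or a list of three ",
         "4-component ratio vectors", call. = FALSE)
  }
  structure(list(p1 = ps[[1]], p2 = ps[[2]], p3 = ps[[3]]),
            class = "degenerate_codon")
}

is_degenerate_codon <- function(x) inherits(x, "degenerate_codon")

.validate_codon <- function(codon) {
  if (!is_degenerate_codon(codon)) {
    stop("expected a 'degenerate_codon' object", call. = FALSE)
  }
  for (p in codon) {
    stopifnot(length(p) == 4L, all(p >= 0), all(p <= 1),
              abs(sum(p) - 1) < 1e-12)
  }
  invisible(codon)
}

#' @export
print.degenerate_codon <- function(x, ...) {
  cat("Degenerate codon (P over A/C/G/T per codon position):\n")
  m <- rbind(x$p1, x$p2, x$p3)
  dimnames(m) <- list(paste0("pos", 1:3), .BASES)
  print(round(m, 4))
  invisible(x)
}

#' Amber suppression policy
#'
#' In supE amber-suppressor E. coli hosts (such as TG1) the amber stop codon
#' TAG is read through as glutamine, so amber-containing clones are displayed
#' and their inserts translate with Gln at the amber position. `mode
#' = "amber-to-gln"` folds the TAG codon mass into Gln in analytic
#' distributions and translates TAG as `Q`. The suppression `efficiency`
#' (fraction of read-through, literature estimates around 41-61% for TG1) is
#' a *selection weight* used only by the screen simulator -- it never rescales
#' analytic codon distributions.
#'
#' @param mode `"amber-to-gln"` (default) or `"none"`.
#' @param efficiency Display/selection weight of amber-containing clones,
#'   in `[0, 1]`. Default 0.5, the midpoint of the cited 41-61% range.
#' @return A `suppression_policy` object.
#' @export
suppression_policy <- function(mode = c("amber-to-gln", "none"),
                               efficiency = 0.5) {
  mode <- match.arg(mode)
  if (!is.numeric(efficiency) || length(efficiency) != 1L ||
      is.na(efficiency) || efficiency < 0 || efficiency > 1) {
    stop("efficiency must be a single number in [0, 1]", call. = FALSE)
  }
  structure(list(mode = mode, efficiency = efficiency),
            class = "suppression_policy")
}

.validate_policy <- function(policy) {
  if (!inherits(policy, "suppression_policy")) {
    stop("expected a 'suppression_policy' object (see suppression_policy())",
         call. = FALSE)
  }
  invisible(policy)
}

#' @export
print.suppression_policy <- function(x, ...) {
  cat("Suppression policy:", x$mode)
  if (x$mode == "amber-to-gln") {
    cat(sprintf(" (simulator selection efficiency s = %.2f)", x$efficiency))
  }
  cat("\n")
  invisible(x)
}

# Probability of each of the 64 codons under a degenerate codon model:
# product of the three per-position marginals.
codon_probabilities <- function(codon) {
  .validate_codon(codon)
  b1 <- substr(.ALL_CODONS, 1, 1)
  b2 <- substr(.ALL_CODONS, 2, 2)
  b3 <- substr(.ALL_CODONS, 3, 3)
  stats::setNames(codon$p1[b1] * codon$p2[b2] * codon$p3[b3], .ALL_CODONS)
}

#' Exact amino-acid distribution of a degenerate codon
#'
#' Sums, over all 64 codons, the product of the per-position nucleotide
#' probabilities, accumulated by the residue each codon encodes under the
#' standard genetic code. Under the `"amber-to-gln"` policy the TAG mass is
#' moved from the stop symbol `*` to Gln (Q); this is a deterministic
#' recoding, not scaled by the suppression efficiency. By default the
#' distribution is reported over the full codon mass *including* residual
#' stop mass, i.e. stop codons are not renormalized away.
#'
#' @param codon A [parse_degenerate_codon()] object.
#' @param policy A [suppression_policy()]; default amber-to-Gln.
#' @param renormalize If `TRUE`, drop residual stop mass and rescale the
#'   residue probabilities to sum to 1. Default `FALSE`.
#' @return Named numeric vector over the 20 amino acids and `*`, summing to 1
#'   (over the 20 amino acids if `renormalize = TRUE`).
#' @examples
#' soft <- parse_degenerate_codon(
#'   list(c(10, 10, 70, 10), c(70, 10, 10, 10), c(10, 10, 10, 70)))
#' codon_aa_distribution(soft)[c("D", "E", "M", "W")]
#' @export
codon_aa_distribution <- function(codon, policy = suppression_policy(),
                                  renormalize = FALSE) {
  .validate_policy(policy)
  pr <- codon_probabilities(codon)
  aa <- Biostrings::GENETIC_CODE[names(pr)]
  if (policy$mode == "amber-to-gln") {
    aa[names(pr) == .AMBER] <- "Q"
  }
  d <- stats::setNames(numeric(length(.AA_LEVELS)), .AA_LEVELS)
  agg <- tapply(pr, aa, sum)
  d[names(agg)] <- agg
  if (renormalize) {
    d <- d[.AA_LEVELS != "*"]
    if (sum(d) <= 0) stop("codon has no stop-free mass", call. = FALSE)
    d <- d / sum(d)
  }
  d
}

#' Number of distinct stop codons a degenerate codon can produce
#'
#' Counts how many of TAA, TAG, TGA have nonzero probability under the codon
#' model, irrespective of any suppression policy. NNK admits exactly one
#' (the amber codon TAG), which is why it is the standard hard-randomization
#' codon in amber-suppressor hosts.
#'
#' @inheritParams codon_aa_distribution
#' @return Integer in 0..3.
#' @export
count_stop_codons <- function(codon) {
  pr <- codon_probabilities(codon)
  sum(pr[.STOP_CODONS] > 0)
}
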