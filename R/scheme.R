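#' Position specifications for a library scheme
#'
#' A library scheme position is either fixed (always the same residue,
#' encoded by one specific codon in the oligonucleotide) or randomized
#' (encoded by a degenerate codon). `position_fixed()` and
#' `position_randomized()` build the two kinds.
#'
#' @param residue One-letter amino-acid code of a fixed position.
#' @param codon For a fixed position, the specific codon used in the
#'   oligonucleotide (a 3-letter ACGT string); for a randomized position, a
#'   [parse_degenerate_codon()] object or something coercible to one (an
#'   IUPAC triplet string or a ratio-vector list).
#' @return A `position_spec` object.
#' @name position_spec
NULL

#' @rdname position_spec
#' @export
position_fixed <- function(residue, codon) {
  if (!is.character(residue) || length(residue) != 1L || nchar(residue) != 1L ||
      !(residue %in% setdiff(.AA_LEVELS, "*"))) {
    stop("residue must be a single one-letter amino-acid code", call. = FALSE)
  }
  if (!is.character(codon) || nchar(codon) != 3L ||
      grepl("[^ACGT]", codon)) {
    stop("fixed-position codon must be a 3-letter ACGT string", call. = FALSE)
  }
  if (unname(Biostrings::GENETIC_CODE[codon]) != residue) {
    stop("codon ", codon, " does not encode residue ", residue, call. = FALSE)
  }
  structure(list(mode = "fixed", residue = residue,
                 codon = parse_degenerate_codon(codon)),
            class = "position_spec")
}

#' @rdname position_spec
#' @export
position_randomized <- function(codon) {
  if (!is_degenerate_codon(codon)) codon <- parse_degenerate_codon(codon)
  structure(list(mode = "randomized", residue = NULL, codon = codon),
            class = "position_spec")
}

#' Library scheme: ordered position specs plus flanking vector context
#'
#' The generative model of a focused peptide library: an ordered list of
#' per-position codon specifications (fixed or degenerate) and the fixed
#' vector nucleotide sequence adjoining the insert on each side. The flanks
#' are what anchors insert extraction in sequencing reads.
#'
#' @param positions List of [position_fixed()] / [position_randomized()]
#'   specs, in peptide order (position 1 first).
#' @param flank5,flank3 Nonempty ACGT strings: vector sequence immediately
#'   5' and 3' of the insert, in insert orientation.
#' @return A `library_scheme` with `positions`, `flank5`, `flank3` and
#'   `insert_length_nt` (= 3 x number of positions).
#' @export
library_scheme <- function(positions, flank5, flank3) {
  if (!is.list(positions) || length(positions) == 0L ||
      !all(vapply(positions, inherits, logical(1), "position_spec"))) {
    stop("positions must be a nonempty list of position_spec objects",
         call. = FALSE)
  }
  for (fl in list(flank5 = flank5, flank3 = flank3)) {
    if (!is.character(fl) || length(fl) != 1L || nchar(fl) == 0L ||
        grepl("[^ACGT]", fl)) {
      stop("flanks must be nonempty ACGT strings without ambiguity codes",
           call. = FALSE)
    }
  }
  structure(list(positions = positions,
                 flank5 = flank5, flank3 = flank3,
                 insert_length_nt = 3L * length(positions)),
            class = "library_scheme")
}

.validate_scheme <- function(scheme) {
  if (!inherits(scheme, "library_scheme")) {
    stop("expected a 'library_scheme' object", call. = FALSE)
  }
  stopifnot(scheme$insert_length_nt == 3L * length(scheme$positions))
  invisible(scheme)
}

#' @export
print.library_scheme <- function(x, ...) {
  cat(sprintf("Library scheme: %d positions, %d nt insert\n",
              length(x$positions), x$insert_length_nt))
  for (i in seq_along(x$positions)) {
    p <- x$positions[[i]]
    if (p$mode == "fixed") {
      cat(sprintf("  %d: fixed %s\n", i, p$residue))
    } else {
      cat(sprintf("  %d: randomized\n", i))
    }
  }
  cat("  flank5:", x$flank5, "\n  flank3:", x$flank3, "\n")
  invisible(x)
}

#' The focused IgG-binding nonapeptide library scheme
#'
#' The built-in nine-position focused library around the IgG Fc-binding
#' parent peptide GSYWYDVWF: Gly1 fixed (GGT); hard NNK randomization at
#' positions 2 and 7; conservative Tyr/Phe variation (TWT) at positions 3, 5
#' and 9; Trp fixed (TGG) at positions 4 and 8; and soft randomization at
#' position 6 biased towards the parent aspartate with a 70/10/10/10
#' nucleotide doping scheme per codon position
#' (70% G at nt 1, 70% A at nt 2, 70% T at nt 3). Flanks are the vector
#' context adjoining the 27-bp insert (NcoI side 5', NotI side 3').
#'
#' @return A [library_scheme()].
#' @export
igg_focused_scheme <- function() {
  soft6 <- parse_degenerate_codon(list(
    c(10, 10, 70, 10),   # 70% G
    c(70, 10, 10, 10),   # 70% A
    c(10, 10, 10, 70)    # 70% T
  ))
  library_scheme(
    positions = list(
      position_fixed("G", "GGT"),
      position_randomized("NNK"),
      position_randomized("TWT"),
      position_fixed("W", "TGG"),
      position_randomized("TWT"),
      position_randomized(soft6),
      position_randomized("NNK"),
      position_fixed("W", "TGG"),
      position_randomized("TWT")
    ),
    flank5 = "AATTCCATGGCC",
    flank3 = "GCGGCCGCCTAACGTAACGACCAG"
  )
}

#' Expected amino-acid distribution at each scheme position
#'
#' Fixed positions yield a point mass on their residue; randomized positions
#' yield the exact [codon_aa_distribution()] of their degenerate codon under
#' the given suppression policy. Distributions are over the full codon mass
#' including residual stop probability (no renormalization) unless
#' `renormalize = TRUE`.
#'
#' @param scheme A [library_scheme()].
#' @param policy A [suppression_policy()].
#' @param renormalize Drop stop mass and rescale (default `FALSE`).
#' @return List of named probability vectors (one per position) over the 20
#'   amino acids and `*`.
#' @export
expected_position_frequencies <- function(scheme,
                                          policy = suppression_policy(),
                                          renormalize = FALSE) {
  .validate_scheme(scheme)
  lapply(scheme$positions, function(p) {
    if (p$mode == "fixed") {
      d <- stats::setNames(numeric(length(.AA_LEVELS)), .AA_LEVELS)
      d[p$residue] <- 1
      if (renormalize) d <- d[.AA_LEVELS != "*"]
      d
    } else {
      codon_aa_distribution(p$codon, policy, renormalize = renormalize)
    }
  })
}

#' Expected per-position frequencies as a long table
#'
#' @inheritParams expected_position_frequencies
#' @param drop_zero Drop residues with zero expected frequency (default
#'   `TRUE`).
#' @return data.frame with columns `position`, `residue`,
#'   `expected_frequency`.
#' @export
expected_frequency_table <- function(scheme, policy = suppression_policy(),
                                     renormalize = FALSE, drop_zero = TRUE) {
  dists <- expected_position_frequencies(scheme, policy, renormalize)
  out <- do.call(rbind, lapply(seq_along(dists), function(i) {
    data.frame(position = i, residue = names(dists[[i]]),
               expected_frequency = unname(dists[[i]]))
  }))
  if (drop_zero) out <- out[out$expected_frequency > 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Position-weight matrix of expected residue frequencies
#'
#' @inheritParams expected_position_frequencies
#' @return Numeric matrix, residues (rows, 20 amino acids and `*`) by
#'   positions (columns); suitable for logo rendering.
#' @export
expected_frequency_matrix <- function(scheme, policy = suppression_policy(),
                                      renormalize = FALSE) {
  dists <- expected_position_frequencies(scheme, policy, renormalize)
  m <- do.call(cbind, dists)
  colnames(m) <- seq_along(dists)
  m
}

# Per-position stop-free residue distributions (unnormalized: entries sum to
# the stop-free mass of the position), with amber handled per policy.
.stopfree_position_dists <- function(scheme, policy) {
  lapply(expected_position_frequencies(scheme, policy), function(d) {
    d <- d[names(d) != "*"]
    d[d > 0]
  })
}

#' Theoretical diversity of a library scheme
#'
#' The number of distinct stop-free peptide sequences reachable with nonzero
#' probability. Amber codons are read according to the policy
#' (`"amber-to-gln"` collapses TAG into Gln before counting); peptides that
#' would contain an unsuppressed stop are excluded. Because positions are
#' independent, the count is the product of per-position distinct stop-free
#' residue counts; it is exact (integer-valued double, well below 2^53 for
#' schemes with up to 12 randomized positions).
#'
#' @inheritParams expected_position_frequencies
#' @return The number of distinct peptides, as a numeric scalar.
#' @examples
#' peptide_space_size(igg_focused_scheme())  # 64000
#' @export
peptide_space_size <- function(scheme, policy = suppression_policy()) {
  counts <- vapply(.stopfree_position_dists(scheme, policy), length, integer(1))
  size <- prod(as.numeric(counts))
  if (size >= 2^53) {
    stop("peptide space too large for exact integer arithmetic", call. = FALSE)
  }
  size
}

#' Enumerate the stop-free peptide space with exact prior probabilities
#'
#' Expands the full cross-product of per-position stop-free residue sets and
#' attaches each peptide's exact prior probability (product of per-position
#' residue probabilities under the codon models, amber handled per policy).
#' Probabilities sum to the total stop-free mass of the scheme, i.e. they are
#' *not* renormalized over the stop-free space.
#'
#' @inheritParams expected_position_frequencies
#' @param cap Refuse to enumerate spaces larger than this (default 1e6).
#' @return data.frame with columns `peptide` (character, lexicographic
#'   order) and `probability`.
#' @export
enumerate_peptide_space <- function(scheme, policy = suppression_policy(),
                                    cap = 1e6) {
  size <- peptide_space_size(scheme, policy)
  if (size > cap) {
    stop("peptide space size ", format(size, big.mark = ","),
         " exceeds enumeration cap ", format(cap, big.mark = ","),
         call. = FALSE)
  }
  dists <- .stopfree_position_dists(scheme, policy)
  grids <- expand.grid(lapply(dists, names), KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)
  prob <- Reduce(`*`, lapply(seq_along(dists), function(i) {
    unname(dists[[i]][grids[[i]]])
  }))
  peptide <- do.call(paste0, grids)
  ord <- order(peptide, method = "radix")
  data.frame(peptide = peptide[ord], probability = prob[ord])
}

#' Read or write a library scheme as a structured YAML config
#'
#' The config has a `positions` list (entries `{fixed: G, codon: GGT}`,
#' `{codon: NNK}` or `{codon_ratios: [[...],[...],[...]]}` in peptide order)
#' and `flank5` / `flank3` strings.
#'
#' @param path File path.
#' @param scheme A [library_scheme()].
#' @return `read_scheme()` returns a [library_scheme()];
#'   `write_scheme()` returns `path` invisibly.
#' @name scheme_io
NULL

#' @rdname scheme_io
#' @export
read_scheme <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$positions) || is.null(cfg$flank5) || is.null(cfg$flank3)) {
    stop("scheme config must contain 'positions', 'flank5' and 'flank3'",
         call. = FALSE)
  }
  positions <- lapply(cfg$positions, function(p) {
    if (!is.null(p$fixed)) {
      position_fixed(p$fixed, p$codon)
    } else if (!is.null(p$codon_ratios)) {
      position_randomized(parse_degenerate_codon(
        lapply(p$codon_ratios, as.numeric)))
    } else if (!is.null(p$codon)) {
      position_randomized(p$codon)
    } else {
      stop("each position entry needs 'fixed', 'codon' or 'codon_ratios'",
           call. = FALSE)
    }
  })
  library_scheme(positions, cfg$flank5, cfg$flank3)
}

#' @rdname scheme_io
#' @export
write_scheme <- function(scheme, path) {
  .validate_scheme(scheme)
  positions <- lapply(scheme$positions, function(p) {
    if (p$mode == "fixed") {
      codon <- paste0(vapply(p$codon, function(v) names(v)[v == 1][1],
                             character(1)), collapse = "")
      list(fixed = p$residue, codon = codon)
    } else {
      list(codon_ratios = lapply(p$codon, function(v) as.numeric(v)))
    }
  })
  yaml::write_yaml(list(positions = positions,
                        flank5 = scheme$flank5, flank3 = scheme$flank3),
                   path)
  invisible(path)
}
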