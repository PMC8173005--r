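# Deterministic planted-binder sets for demonstration and validation
# screens.

#' Build a planted set of motif variants around a parent peptide
#'
#' Constructs a deterministic set of `n` peptides -- the parent plus
#' single-position variants at the scheme's randomized positions -- with
#' selection weights log-spaced between `w_min` and `w_max`; the parent
#' receives the largest weight. Such a set emulates the outcome of a
#' focused-library screen in which the true binders are variants of the
#' lead sequence, and makes planted-motif recovery checks (hit ranking,
#' consensus derivation) well defined.
#'
#' @param scheme A [library_scheme()].
#' @param policy A [suppression_policy()] (defines each position's
#'   reachable residue set).
#' @param parent Parent peptide (must be reachable under the scheme).
#' @param n Total number of planted peptides (parent included).
#' @param w_min,w_max Weight range (log-spaced).
#' @return data.frame with columns `peptide`, `weight`; first row is the
#'   parent at `w_max`.
#' @export
planted_variants <- function(scheme, policy = suppression_policy(),
                             parent = "GSYWYNVWF", n = 50,
                             w_min = 10, w_max = 1000) {
  .validate_scheme(scheme)
  if (nchar(parent) != length(scheme$positions)) {
    stop("parent length does not match the scheme", call. = FALSE)
  }
  dists <- .stopfree_position_dists(scheme, policy)
  rand_pos <- which(vapply(scheme$positions, function(p) p$mode,
                           character(1)) == "randomized")
  for (j in seq_along(dists)) {
    if (!substr(parent, j, j) %in% names(dists[[j]])) {
      stop("parent residue at position ", j,
           " is unreachable under the scheme", call. = FALSE)
    }
  }
  variants <- character(0)
  round <- 0L
  while (length(variants) < n - 1L) {
    round <- round + 1L
    added <- FALSE
    for (j in rand_pos) {
      alts <- setdiff(names(dists[[j]]), substr(parent, j, j))
      if (round <= length(alts)) {
        v <- parent
        substr(v, j, j) <- alts[round]
        if (!v %in% variants) {
          variants <- c(variants, v)
          added <- TRUE
          if (length(variants) == n - 1L) break
        }
      }
    }
    if (!added) {
      stop("scheme too small to derive ", n - 1L, " distinct variants",
           call. = FALSE)
    }
  }
  w <- exp(seq(log(w_min), log(w_max), length.out = n))
  data.frame(peptide = c(parent, variants),
             weight = c(w[n], w[seq_len(n - 1L)]))
}
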