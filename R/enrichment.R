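# Enrichment-factor computation: per-position residue frequencies and
# factors versus the pre-screened library, per-peptide factors, replicate
# concordance, hit calling, and consensus derivation.

#' Per-position residue frequencies of a counted sample
#'
#' For each peptide position, the fraction of accepted reads whose peptide
#' carries each residue there. Fixed positions trivially concentrate on
#' their residue.
#'
#' @param table A `peptide_count_table`.
#' @param scheme A [library_scheme()] (defines the number of positions).
#' @return A data.frame (class `position_frequency_table`) with columns
#'   `position`, `residue`, `frequency`; attribute `n_reads` holds the
#'   accepted-read total. Frequencies sum to 1 within each position.
#' @export
position_frequencies <- function(table, scheme) {
  stopifnot(inherits(table, "peptide_count_table"))
  .validate_scheme(scheme)
  n <- sum(table$counts)
  if (n == 0L) {
    stop("empty sample: no accepted reads to compute frequencies from",
         call. = FALSE)
  }
  peptides <- names(table$counts)
  counts <- as.numeric(table$counts)
  out <- do.call(rbind, lapply(seq_along(scheme$positions), function(j) {
    res <- substr(peptides, j, j)
    agg <- rowsum(counts, res)
    data.frame(position = j, residue = rownames(agg),
               frequency = as.numeric(agg) / n)
  }))
  rownames(out) <- NULL
  out <- out[order(out$position, out$residue, method = "radix"), ]
  rownames(out) <- NULL
  attr(out, "n_reads") <- n
  class(out) <- c("position_frequency_table", "data.frame")
  out
}

#' Residue-level enrichment factors versus the pre-screened library
#'
#' For every (position, residue) with nonzero library frequency, the ratio
#' of its eluate frequency to its library frequency. No pseudocount is
#' applied at residue level: per-position library frequencies are large by
#' design. Residues absent from the eluate but present in the library get
#' factor 0; residues absent from the library are not emitted.
#'
#' @param eluate,library [position_frequencies()] tables over the same
#'   scheme.
#' @return data.frame with columns `position`, `residue`, `freq_eluate`,
#'   `freq_library`, `enrichment`.
#' @export
residue_enrichment <- function(eluate, library) {
  stopifnot(inherits(eluate, "position_frequency_table"),
            inherits(library, "position_frequency_table"))
  lib <- library[library$frequency > 0, , drop = FALSE]
  names(lib)[names(lib) == "frequency"] <- "freq_library"
  elu <- eluate
  names(elu)[names(elu) == "frequency"] <- "freq_eluate"
  out <- merge(lib, elu, by = c("position", "residue"), all.x = TRUE)
  out$freq_eluate[is.na(out$freq_eluate)] <- 0
  out$enrichment <- out$freq_eluate / out$freq_library
  out <- out[order(out$position, out$residue, method = "radix"),
             c("position", "residue", "freq_eluate", "freq_library",
               "enrichment")]
  rownames(out) <- NULL
  out
}

#' Per-peptide enrichment factors versus the pre-screened library
#'
#' For each peptide detected at least once in either sample,
#' `E(p) = [(c_elu(p) + a) / (N_elu + aV)] / [(c_lib(p) + a) / (N_lib + aV)]`
#' where `a` is the pseudocount and `V` the number of distinct peptides
#' observed in the union of the two samples. The default `a = 0.5`
#' (Jeffreys-style) keeps factors finite for peptides unobserved in the
#' deeply-but-not-exhaustively sequenced library. With `a = 0`, peptides
#' absent from the library are skipped with a warning.
#'
#' @param eluate,library `peptide_count_table`s.
#' @param pseudocount Nonnegative pseudocount `a` (default 0.5).
#' @return data.frame (class `peptide_enrichment`) with columns `peptide`,
#'   `count_eluate`, `count_library`, `freq_eluate`, `freq_library`,
#'   `enrichment`; attributes `pseudocount`, `n_eluate`, `n_library`,
#'   `v_union` record the estimator's ingredients.
#' @export
peptide_enrichment <- function(eluate, library, pseudocount = 0.5) {
  stopifnot(inherits(eluate, "peptide_count_table"),
            inherits(library, "peptide_count_table"))
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L ||
      is.na(pseudocount) || pseudocount < 0) {
    stop("pseudocount must be a single nonnegative number", call. = FALSE)
  }
  peptides <- sort(union(names(eluate$counts), names(library$counts)),
                   method = "radix")
  v <- length(peptides)
  if (v == 0L) stop("both samples are empty", call. = FALSE)
  c_elu <- numeric(v); c_lib <- numeric(v)
  c_elu[match(names(eluate$counts), peptides)] <- eluate$counts
  c_lib[match(names(library$counts), peptides)] <- library$counts
  n_elu <- sum(eluate$counts)
  n_lib <- sum(library$counts)
  out <- data.frame(peptide = peptides,
                    count_eluate = as.integer(c_elu),
                    count_library = as.integer(c_lib))
  if (pseudocount == 0) {
    absent <- out$count_library == 0L
    if (any(absent)) {
      warning(sum(absent), " peptide(s) absent from the library skipped ",
              "(pseudocount 0)", call. = FALSE)
      out <- out[!absent, , drop = FALSE]
    }
  }
  a <- pseudocount
  out$freq_eluate <- (out$count_eluate + a) / (n_elu + a * v)
  out$freq_library <- (out$count_library + a) / (n_lib + a * v)
  out$enrichment <- out$freq_eluate / out$freq_library
  rownames(out) <- NULL
  attr(out, "pseudocount") <- a
  attr(out, "n_eluate") <- n_elu
  attr(out, "n_library") <- n_lib
  attr(out, "v_union") <- v
  class(out) <- c("peptide_enrichment", "data.frame")
  out
}

#' Concordance of per-peptide enrichment between two replicate screens
#'
#' Joins the two replicate factor tables on the union of peptides detected
#' at least once in at least one replicate *eluate*, and reports the Pearson
#' correlation of log10 enrichment factors over that union together with the
#' joined table. A peptide detected in only one replicate pair receives, in
#' the other, the zero-count factor implied by that replicate's pseudocount
#' (with pseudocount 0 such peptides are dropped with a warning).
#'
#' @param rep_a,rep_b [peptide_enrichment()] tables computed with the same
#'   pseudocount against the same library.
#' @return List (class `replicate_concordance`) with `n` (union size),
#'   `pearson_log10` (`NA` when the union has fewer than 3 peptides or a
#'   replicate is constant), and `table` (columns `peptide`,
#'   `count_eluate_a`, `count_eluate_b`, `enrichment_a`, `enrichment_b`).
#' @export
replicate_concordance <- function(rep_a, rep_b) {
  stopifnot(inherits(rep_a, "peptide_enrichment"),
            inherits(rep_b, "peptide_enrichment"))
  a <- attr(rep_a, "pseudocount"); b <- attr(rep_b, "pseudocount")
  if (!isTRUE(all.equal(a, b))) {
    stop("replicates must be computed with identical pseudocounts",
         call. = FALSE)
  }
  union_pep <- sort(union(rep_a$peptide[rep_a$count_eluate > 0],
                          rep_b$peptide[rep_b$count_eluate > 0]),
                    method = "radix")
  fill_factor <- function(rep, peptides) {
    i <- match(peptides, rep$peptide)
    e <- rep$enrichment[i]
    ce <- rep$count_eluate[i]
    ce[is.na(ce)] <- 0L
    missing <- is.na(e)
    if (any(missing)) {
      pc <- attr(rep, "pseudocount")
      if (pc == 0) {
        e[missing] <- NA_real_
      } else {
        v <- attr(rep, "v_union")
        e0 <- (pc / (attr(rep, "n_eluate") + pc * v)) /
          (pc / (attr(rep, "n_library") + pc * v))
        e[missing] <- e0
      }
    }
    list(e = e, ce = ce)
  }
  fa <- fill_factor(rep_a, union_pep)
  fb <- fill_factor(rep_b, union_pep)
  tab <- data.frame(peptide = union_pep,
                    count_eluate_a = fa$ce, count_eluate_b = fb$ce,
                    enrichment_a = fa$e, enrichment_b = fb$e)
  drop <- is.na(tab$enrichment_a) | is.na(tab$enrichment_b)
  if (any(drop)) {
    warning(sum(drop), " peptide(s) without a defined factor in one ",
            "replicate dropped (pseudocount 0)", call. = FALSE)
    tab <- tab[!drop, , drop = FALSE]
  }
  rownames(tab) <- NULL
  r <- NA_real_
  if (nrow(tab) >= 3L) {
    la <- log10(tab$enrichment_a); lb <- log10(tab$enrichment_b)
    ok <- is.finite(la) & is.finite(lb)
    if (sum(ok) >= 3L && stats::sd(la[ok]) > 0 && stats::sd(lb[ok]) > 0) {
      r <- stats::cor(la[ok], lb[ok])
    }
  }
  structure(list(n = nrow(tab), pearson_log10 = r, table = tab),
            class = "replicate_concordance")
}

#' @export
print.replicate_concordance <- function(x, ...) {
  cat(sprintf(
    "Replicate concordance: N = %d peptides, Pearson r (log10 factors) = %s\n",
    x$n, ifelse(is.na(x$pearson_log10), "undefined",
                sprintf("%.3f", x$pearson_log10))))
  invisible(x)
}

#' Call true hits from a replicate-joined enrichment table
#'
#' A true hit is a peptide enriched (factor above `min_factor`) in *both*
#' parallel replicate screens -- the replicate-concordance rule that cancels
#' nonspecific background carryover. Hits are scored by the geometric mean
#' of the two factors and ranked descending, ties broken lexicographically
#' by peptide sequence.
#'
#' @param joined A [replicate_concordance()] result or its `table`.
#' @param min_factor Enrichment threshold both replicates must exceed
#'   (default 1.0; strict inequality).
#' @param top Optional: keep only the `top` highest-ranked hits.
#' @return data.frame (class `hit_list`) with columns `rank`, `peptide`,
#'   `enrichment_a`, `enrichment_b`, `score`.
#' @export
call_hits <- function(joined, min_factor = 1.0, top = NULL) {
  if (inherits(joined, "replicate_concordance")) joined <- joined$table
  stopifnot(is.data.frame(joined),
            all(c("peptide", "enrichment_a", "enrichment_b") %in%
                  names(joined)))
  if (!is.numeric(min_factor) || min_factor < 0) {
    stop("min_factor must be nonnegative", call. = FALSE)
  }
  keep <- joined$enrichment_a > min_factor & joined$enrichment_b > min_factor
  hits <- joined[keep, c("peptide", "enrichment_a", "enrichment_b"),
                 drop = FALSE]
  hits$score <- sqrt(hits$enrichment_a * hits$enrichment_b)
  ord <- order(-hits$score, hits$peptide, method = "radix")
  hits <- hits[ord, , drop = FALSE]
  if (!is.null(top)) hits <- utils::head(hits, top)
  hits <- cbind(rank = seq_len(nrow(hits)), hits)
  rownames(hits) <- NULL
  class(hits) <- c("hit_list", "data.frame")
  hits
}

#' Consensus peptide from residue-level enrichment factors
#'
#' For each randomized position, the residue maximizing the mean enrichment
#' factor across the selected conditions and replicates (lexicographic
#' tie-break); fixed positions keep their residue. Note that a consensus
#' built position-by-position need not itself be a strongly enriched
#' peptide: cooperative interactions among randomized residues are invisible
#' at this level.
#'
#' @param factors data.frame of residue-level factors with columns
#'   `position`, `residue`, `enrichment`, and optionally `condition` /
#'   `replicate` (e.g. stacked [residue_enrichment()] outputs).
#' @param scheme The [library_scheme()] (identifies fixed positions).
#' @param conditions Optional subset of conditions to aggregate over.
#' @return The consensus peptide as a character scalar.
#' @export
consensus_peptide <- function(factors, scheme, conditions = NULL) {
  .validate_scheme(scheme)
  stopifnot(is.data.frame(factors),
            all(c("position", "residue", "enrichment") %in% names(factors)))
  if (!is.null(conditions) && "condition" %in% names(factors)) {
    factors <- factors[factors$condition %in% conditions, , drop = FALSE]
  }
  out <- character(length(scheme$positions))
  for (j in seq_along(scheme$positions)) {
    p <- scheme$positions[[j]]
    if (p$mode == "fixed") {
      out[j] <- p$residue
      next
    }
    f <- factors[factors$position == j, , drop = FALSE]
    if (nrow(f) == 0L) {
      stop("no residue-level factors available for randomized position ", j,
           call. = FALSE)
    }
    agg <- tapply(f$enrichment, f$residue, mean)
    best <- names(agg)[order(-agg, names(agg), method = "radix")][1]
    out[j] <- best
  }
  paste0(out, collapse = "")
}
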