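# Insert extraction and per-sample peptide counting.
#
# Reads are accepted when the anchor_len-suffix of flank5 and the
# anchor_len-prefix of flank3 both occur (exactly) in the read, in order,
# separated by exactly insert_length_nt bases. The search runs on both the
# read and its reverse complement; a minus-strand hit is reported in insert
# orientation. Exactly one candidate placement across both strands is
# required; more than one is rejected as ambiguous placement (a sub-reason
# of no-flank).

.REJECT_REASONS <- c("no_flank", "ambiguous_placement", "wrong_length",
                     "ambiguous_base", "unsuppressed_stop")

# Vectorized placement search on one strand. Returns, per read, the number
# of valid placements, the insert start of the first valid placement, and
# whether both anchors were seen in order at any spacing.
.scan_strand <- function(seqs, anchor5, anchor3, insert_len) {
  n <- length(seqs)
  m5 <- Biostrings::vmatchPattern(anchor5, seqs)
  m3 <- Biostrings::vmatchPattern(anchor3, seqs)
  n5 <- S4Vectors::elementNROWS(m5)
  n3 <- S4Vectors::elementNROWS(m3)
  d5 <- data.frame(read = rep.int(seq_len(n), n5),
                   end5 = unlist(Biostrings::endIndex(m5), use.names = FALSE))
  d3 <- data.frame(read = rep.int(seq_len(n), n3),
                   start3 = unlist(Biostrings::startIndex(m3), use.names = FALSE))
  pairs <- merge(d5, d3, by = "read")
  pairs <- pairs[pairs$start3 > pairs$end5, , drop = FALSE]
  in_order <- tabulate(pairs$read, nbins = n) > 0L
  ok <- pairs[pairs$start3 - pairs$end5 - 1L == insert_len, , drop = FALSE]
  n_valid <- tabulate(ok$read, nbins = n)
  start <- rep(NA_integer_, n)
  if (nrow(ok) > 0L) {
    first <- ok[!duplicated(ok$read), , drop = FALSE]
    start[first$read] <- first$end5 + 1L
  }
  list(n_valid = n_valid, start = start, in_order = in_order)
}

# Batch insert extraction. Returns per-read insert (NA when rejected) and
# rejection reason (NA when accepted).
.extract_inserts <- function(sequences, scheme, anchor_len = 12L) {
  .validate_scheme(scheme)
  anchor_len <- as.integer(anchor_len)
  if (anchor_len < 8L) stop("anchor_len must be >= 8", call. = FALSE)
  if (nchar(scheme$flank5) < anchor_len || nchar(scheme$flank3) < anchor_len) {
    stop("scheme flanks must be at least anchor_len long", call. = FALSE)
  }
  anchor5 <- substr(scheme$flank5,
                    nchar(scheme$flank5) - anchor_len + 1L,
                    nchar(scheme$flank5))
  anchor3 <- substr(scheme$flank3, 1L, anchor_len)
  L <- scheme$insert_length_nt

  fwd <- Biostrings::DNAStringSet(sequences)
  rev <- Biostrings::reverseComplement(fwd)
  sf <- .scan_strand(fwd, anchor5, anchor3, L)
  sr <- .scan_strand(rev, anchor5, anchor3, L)

  n <- length(sequences)
  insert <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)

  n_total <- sf$n_valid + sr$n_valid
  take_f <- n_total == 1L & sf$n_valid == 1L
  take_r <- n_total == 1L & sr$n_valid == 1L
  if (any(take_f)) {
    insert[take_f] <- substr(as.character(fwd[take_f]),
                             sf$start[take_f], sf$start[take_f] + L - 1L)
  }
  if (any(take_r)) {
    insert[take_r] <- substr(as.character(rev[take_r]),
                             sr$start[take_r], sr$start[take_r] + L - 1L)
  }
  reason[n_total > 1L] <- "ambiguous_placement"
  miss <- n_total == 0L
  reason[miss & (sf$in_order | sr$in_order)] <- "wrong_length"
  reason[miss & !(sf$in_order | sr$in_order)] <- "no_flank"

  has_n <- !is.na(insert) & grepl("N", insert, fixed = TRUE)
  reason[has_n] <- "ambiguous_base"
  insert[has_n] <- NA_character_

  list(insert = insert, reason = reason)
}

#' Extract the library insert from a single read
#'
#' Searches the read and its reverse complement for exact occurrences of the
#' `anchor_len`-suffix of `flank5` and the `anchor_len`-prefix of `flank3`,
#' and accepts if and only if both are found, in order, separated by exactly
#' `insert_length_nt` bases free of N. Minus-strand hits are returned in
#' insert orientation. Multiple distinct candidate placements are rejected
#' as ambiguous placement.
#'
#' @param read A read nucleotide sequence (character scalar, ACGTN).
#' @param scheme A [library_scheme()].
#' @param anchor_len Anchor length (>= 8; default 12). Matching is exact --
#'   no mismatches are tolerated.
#' @return A list with `insert` (the insert sequence, or `NA`) and `reason`
#'   (`NA` when accepted; otherwise one of `"no_flank"`,
#'   `"ambiguous_placement"`, `"wrong_length"`, `"ambiguous_base"`).
#' @export
extract_insert <- function(read, scheme, anchor_len = 12L) {
  stopifnot(is.character(read), length(read) == 1L)
  res <- .extract_inserts(read, scheme, anchor_len)
  list(insert = res$insert[1], reason = res$reason[1])
}

#' Translate an insert under a suppression policy
#'
#' Standard-genetic-code translation of an in-frame insert; TAG is read as
#' Gln under the `"amber-to-gln"` policy. Any remaining stop codon makes the
#' clone untranslatable (it would not display), signalled by `stop = TRUE`.
#'
#' @param insert Nucleotide string, length divisible by 3, alphabet ACGT.
#' @param policy A [suppression_policy()].
#' @return A list with `peptide` (the peptide, or `NA` if a stop remains)
#'   and `stop` (logical).
#' @export
translate_insert <- function(insert, policy = suppression_policy()) {
  stopifnot(is.character(insert), length(insert) == 1L)
  if (nchar(insert) %% 3L != 0L) {
    stop("insert length must be divisible by 3", call. = FALSE)
  }
  if (grepl("[^ACGT]", insert)) {
    stop("insert must contain only A, C, G, T", call. = FALSE)
  }
  pep <- .translate_inserts(insert, policy)
  if (grepl("*", pep, fixed = TRUE)) {
    list(peptide = NA_character_, stop = TRUE)
  } else {
    list(peptide = pep, stop = FALSE)
  }
}

#' Count translated insert peptides in a sample of reads
#'
#' Single pass over the reads: each is subjected to insert extraction
#' ([extract_insert()] semantics, vectorized) and translation
#' ([translate_insert()]); accepted peptides are tallied, rejections are
#' tallied by reason. The result is deterministic and independent of read
#' order.
#'
#' @param reads A FASTQ sample object (from the simulator or
#'   [read_fastq()]), a character vector of read sequences, or a path to a
#'   FASTQ file.
#' @param scheme A [library_scheme()].
#' @param policy A [suppression_policy()].
#' @param anchor_len Anchor length for flank matching (default 12).
#' @param sample Sample label stored on the table.
#' @return A `peptide_count_table`: list with `sample`, `counts` (named
#'   integer vector, peptide -> read count, lexicographic order), and
#'   `totals` (`scanned`, `with_insert`, and a named `rejected` vector over
#'   reasons `no_flank`, `ambiguous_placement`, `wrong_length`,
#'   `ambiguous_base`, `unsuppressed_stop`).
#' @export
count_sample <- function(reads, scheme, policy = suppression_policy(),
                         anchor_len = 12L, sample = "sample") {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    reads <- read_fastq(reads)
  }
  if (inherits(reads, "fastq_sample")) reads <- reads$sequence
  if (!is.character(reads)) {
    stop("reads must be a FASTQ sample, a character vector, or a file path",
         call. = FALSE)
  }
  scanned <- length(reads)
  rejected <- stats::setNames(integer(length(.REJECT_REASONS)),
                              .REJECT_REASONS)
  counts <- stats::setNames(integer(0), character(0))
  with_insert <- 0L
  if (scanned > 0L) {
    ext <- .extract_inserts(reads, scheme, anchor_len)
    tabr <- table(ext$reason)
    rejected[names(tabr)] <- as.integer(tabr)
    ok <- !is.na(ext$insert)
    with_insert <- sum(ok)
    if (with_insert > 0L) {
      peps <- .translate_inserts(ext$insert[ok], policy)
      stopped <- grepl("*", peps, fixed = TRUE)
      rejected["unsuppressed_stop"] <- sum(stopped)
      if (any(!stopped)) {
        tab <- table(peps[!stopped])
        counts <- stats::setNames(as.integer(tab), names(tab))
        counts <- counts[order(names(counts), method = "radix")]
      }
    }
  }
  structure(list(sample = sample, counts = counts,
                 totals = list(scanned = scanned,
                               with_insert = as.integer(with_insert),
                               rejected = rejected)),
            class = "peptide_count_table")
}

#' Build a peptide count table from explicit counts
#'
#' Useful for analyses that start from pre-tabulated counts rather than
#' reads (all totals other than the accepted counts are zero).
#'
#' @param counts Named integer vector or data.frame with columns `peptide`
#'   and `count`.
#' @param sample Sample label.
#' @return A `peptide_count_table`.
#' @export
peptide_count_table <- function(counts, sample = "sample") {
  if (is.data.frame(counts)) {
    counts <- stats::setNames(as.integer(counts$count),
                              as.character(counts$peptide))
  }
  if (is.null(names(counts)) || any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be a named vector of nonnegative integers",
         call. = FALSE)
  }
  counts <- counts[counts > 0]
  counts <- counts[order(names(counts), method = "radix")]
  storage.mode(counts) <- "integer"
  n <- sum(counts)
  structure(list(sample = sample, counts = counts,
                 totals = list(scanned = n, with_insert = n,
                               rejected = stats::setNames(
                                 integer(length(.REJECT_REASONS)),
                                 .REJECT_REASONS))),
            class = "peptide_count_table")
}

#' @export
print.peptide_count_table <- function(x, ...) {
  cat(sprintf("Peptide count table '%s': %d distinct peptides, %d reads\n",
              x$sample, length(x$counts), sum(x$counts)))
  t <- x$totals
  cat(sprintf("  scanned %d | with insert %d | rejected: %s\n",
              t$scanned, t$with_insert,
              paste(sprintf("%s=%d", names(t$rejected), t$rejected),
                    collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.peptide_count_table <- function(x, ...) {
  data.frame(peptide = names(x$counts), count = unname(x$counts))
}

#' Write peptide counts and the rejection summary as TSV
#'
#' @param x A `peptide_count_table`.
#' @param counts_path Path for the `peptide`/`count` TSV.
#' @param summary_path Optional path for the rejection-summary TSV.
#' @param header_comment Optional comment line (prefixed `#`) written atop
#'   each file, e.g. a config hash.
#' @return `counts_path`, invisibly.
#' @export
write_count_table <- function(x, counts_path, summary_path = NULL,
                              header_comment = NULL) {
  stopifnot(inherits(x, "peptide_count_table"))
  .write_tsv(as.data.frame(x), counts_path, header_comment)
  if (!is.null(summary_path)) {
    t <- x$totals
    summ <- data.frame(
      metric = c("scanned", "with_insert", names(t$rejected)),
      reads = c(t$scanned, t$with_insert, unname(t$rejected)))
    .write_tsv(summ, summary_path, header_comment)
  }
  invisible(counts_path)
}

.write_tsv <- function(df, path, header_comment = NULL) {
  con <- file(path, "wb")
  on.exit(close(con))
  if (!is.null(header_comment)) {
    writeLines(paste0("# ", header_comment), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by this package
#'
#' @param path File path; leading `#` comment lines are skipped.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
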