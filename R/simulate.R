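#' Deterministic sub-seed derivation
#'
#' Replicate samples must be statistically independent yet reproducible from
#' one master seed. Sub-seeds are derived by a fixed polynomial string hash:
#' starting from the master seed, fold in each character of `label` and then
#' `replicate` via `h <- (31 * h + v) mod 2147483629`.
#'
#' @param seed Master integer seed.
#' @param label Character label of the stream (e.g. a condition name).
#' @param replicate Integer replicate index.
#' @return An integer usable with [set.seed()].
#' @export
derive_seed <- function(seed, label, replicate = 0L) {
  h <- as.numeric(seed) %% 2147483629
  for (v in utf8ToInt(as.character(label))) {
    h <- (31 * h + v) %% 2147483629
  }
  h <- (31 * h + as.numeric(replicate)) %% 2147483629
  as.integer(h)
}

#' Per-peptide selection weight model
#'
#' Selection in a single-round screen is modeled as proportional retention:
#' each peptide carries a nonnegative weight and the eluate is the library
#' reweighted by it. The model is a baseline weight shared by all peptides,
#' optionally dispersed per peptide by a lognormal factor (emulating the
#' broad, continuous affinity spectrum of a real focused library), plus a
#' planted set of per-peptide overrides (the "true binders"). Clones whose
#' insert carries amber codons are additionally down-weighted by the
#' suppression efficiency `s` per amber codon, since every amber must be
#' read through for the peptide to display.
#'
#' @param baseline Baseline weight for all peptides (default 1).
#' @param planted `NULL`, or a data.frame with columns `peptide`, `weight`
#'   and optionally `condition` (overrides restricted to one condition;
#'   otherwise applied to all conditions).
#' @param baseline_sdlog Standard deviation (log scale) of the lognormal
#'   per-peptide dispersion multiplying the baseline; 0 (default) disables
#'   it.
#' @return A `weight_model` object.
#' @export
weight_model <- function(baseline = 1, planted = NULL, baseline_sdlog = 0) {
  if (!is.numeric(baseline) || baseline < 0) {
    stop("baseline weight must be nonnegative", call. = FALSE)
  }
  if (!is.null(planted)) {
    if (!is.data.frame(planted) ||
        !all(c("peptide", "weight") %in% names(planted))) {
      stop("planted must be a data.frame with columns peptide and weight",
           call. = FALSE)
    }
    if (any(planted$weight < 0)) {
      stop("planted weights must be nonnegative", call. = FALSE)
    }
  }
  if (!is.numeric(baseline_sdlog) || baseline_sdlog < 0) {
    stop("baseline_sdlog must be nonnegative", call. = FALSE)
  }
  structure(list(baseline = baseline, planted = planted,
                 baseline_sdlog = baseline_sdlog),
            class = "weight_model")
}

#' Configuration of a synthetic single-round screen
#'
#' Bundles everything the simulator needs: the library scheme and
#' suppression policy, the elution conditions and replicate count,
#' sequencing depths, the nonspecific background fraction, the selection
#' weight model, an optional synthesis bias, a per-base error rate, and the
#' master seed. Defaults mirror the screen the package models: a naive
#' library sequenced at 184,511 insert-spanning reads and eluates around the
#' reported median of 10,898 reads.
#'
#' @param scheme A [library_scheme()].
#' @param policy A [suppression_policy()].
#' @param conditions Character vector of condition labels.
#' @param replicates Number of replicate eluates per condition (>= 1).
#' @param depth_library Reads in the naive library sample.
#' @param depth_eluate Reads per eluate sample.
#' @param background Background carryover fraction beta in `[0, 1]`: the part
#'   of the eluate that is nonspecifically carried-over library, mixed with
#'   the selection-reweighted part `1 - beta`. Default 0.05.
#' @param weights A [weight_model()].
#' @param synthesis_bias `NULL`, or a named list mapping position indices to
#'   replacement codon specs (IUPAC triplet, ratio list, or
#'   `degenerate_codon`) describing deviations of the synthesized
#'   oligonucleotide pool from the nominal scheme (e.g. a 2:1 Phe:Tyr skew
#'   at TWT positions).
#' @param error_rate Per-base substitution probability applied to every
#'   generated read (default 0).
#' @param seed Master integer seed.
#' @return A `screen_config` object.
#' @export
screen_config <- function(scheme = igg_focused_scheme(),
                          policy = suppression_policy(),
                          conditions = "elution",
                          replicates = 2L,
                          depth_library = 184511L,
                          depth_eluate = 10898L,
                          background = 0.05,
                          weights = weight_model(),
                          synthesis_bias = NULL,
                          error_rate = 0,
                          seed = 1L) {
  .validate_scheme(scheme)
  .validate_policy(policy)
  stopifnot(length(conditions) >= 1L, replicates >= 1L,
            depth_library >= 1L, depth_eluate >= 1L,
            background >= 0, background <= 1,
            error_rate >= 0, error_rate < 1)
  if (!inherits(weights, "weight_model")) {
    stop("weights must be a weight_model object", call. = FALSE)
  }
  structure(list(scheme = scheme, policy = policy,
                 conditions = as.character(conditions),
                 replicates = as.integer(replicates),
                 depth_library = as.integer(depth_library),
                 depth_eluate = as.integer(depth_eluate),
                 background = background,
                 weights = weights,
                 synthesis_bias = synthesis_bias,
                 error_rate = error_rate,
                 seed = as.integer(seed)),
            class = "screen_config")
}

# Scheme with synthesis-bias codon overrides applied.
.biased_scheme <- function(config) {
  scheme <- config$scheme
  bias <- config$synthesis_bias
  if (is.null(bias)) return(scheme)
  for (nm in names(bias)) {
    i <- as.integer(nm)
    if (is.na(i) || i < 1L || i > length(scheme$positions)) {
      stop("synthesis_bias refers to unknown position '", nm, "'",
           call. = FALSE)
    }
    codon <- bias[[nm]]
    if (!is_degenerate_codon(codon)) codon <- parse_degenerate_codon(codon)
    scheme$positions[[i]]$codon <- codon
    scheme$positions[[i]]$mode <- "randomized"
    scheme$positions[[i]]$residue <- NULL
  }
  scheme
}

# The stop-free clone space at codon-class resolution: amber-encoded Gln is
# tracked as a separate symbol "q" so amber selection penalties can be
# applied per clone. Returns per-position symbol/codon tables and the full
# cross-product with normalized stop-free prior probabilities.
.extended_space <- function(scheme, policy) {
  per_pos <- lapply(scheme$positions, function(p) {
    pr <- codon_probabilities(p$codon)
    pr <- pr[pr > 0]
    aa <- unname(Biostrings::GENETIC_CODE[names(pr)])
    if (policy$mode == "amber-to-gln") aa[names(pr) == .AMBER] <- "q"
    keep <- aa != "*"
    pr <- pr[keep]; aa <- aa[keep]
    if (length(pr) == 0L) {
      stop("a position has no stop-free codon mass", call. = FALSE)
    }
    symbols <- sort(unique(aa))
    probs <- vapply(symbols, function(s) sum(pr[aa == s]), numeric(1))
    codons <- lapply(symbols, function(s) pr[aa == s] / sum(pr[aa == s]))
    names(codons) <- symbols
    list(symbols = symbols, probs = probs, codons = codons)
  })
  grids <- expand.grid(lapply(per_pos, function(p) p$symbols),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  prob <- Reduce(`*`, lapply(seq_along(per_pos), function(i) {
    unname(per_pos[[i]]$probs[grids[[i]]])
  }))
  prob <- prob / sum(prob)  # condition on stop-free
  symbol_mat <- as.matrix(grids)
  peptide_ext <- do.call(paste0, grids)
  peptide <- chartr("q", "Q", peptide_ext)
  n_amber <- rowSums(symbol_mat == "q")
  list(per_pos = per_pos, symbol_mat = symbol_mat,
       peptide = peptide, prob = prob, n_amber = n_amber)
}

# Per-peptide selection weights for one condition, aligned to `peptides`
# (collapsed sequences). Lognormal dispersion, if any, is drawn once per
# config (sub-seed "weights") over the lexicographically sorted peptide
# space so that all conditions and replicates see identical weights.
.condition_weights <- function(config, condition, peptides) {
  wm <- config$weights
  uniq <- sort(unique(peptides), method = "radix")
  w <- rep(wm$baseline, length(uniq))
  names(w) <- uniq
  if (wm$baseline_sdlog > 0) {
    set.seed(derive_seed(config$seed, "weights", 0L))
    w <- w * stats::rlnorm(length(uniq), meanlog = 0,
                           sdlog = wm$baseline_sdlog)
  }
  pl <- wm$planted
  if (!is.null(pl)) {
    if ("condition" %in% names(pl)) {
      pl <- pl[is.na(pl$condition) | pl$condition == condition, , drop = FALSE]
    }
    known <- pl$peptide %in% uniq
    if (!all(known)) {
      stop("planted peptides not in the scheme's space: ",
           paste(head(pl$peptide[!known], 3), collapse = ", "),
           call. = FALSE)
    }
    w[pl$peptide] <- pl$weight
  }
  if (all(w[peptides] <= 0)) {
    stop("all selection weights are zero for condition ", condition,
         call. = FALSE)
  }
  unname(w[peptides])
}

# Apply per-base substitution errors to a character vector of equal-length
# sequences.
.apply_errors <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0L) return(seqs)
  len <- nchar(seqs[1])
  for (p in seq_len(len)) {
    hit <- stats::runif(length(seqs)) < rate
    if (any(hit)) {
      cur <- substr(seqs[hit], p, p)
      sub <- vapply(cur, function(b) sample(setdiff(.BASES, b), 1L),
                    character(1), USE.NAMES = FALSE)
      substr(seqs[hit], p, p) <- sub
    }
  }
  seqs
}

.fastq_sample <- function(id, sequence) {
  structure(list(id = id, sequence = sequence,
                 quality = strrep("I", nchar(sequence))),
            class = "fastq_sample")
}

#' @export
print.fastq_sample <- function(x, ...) {
  cat(sprintf("FASTQ sample: %d reads of length %s\n", length(x$sequence),
              paste(unique(nchar(x$sequence[seq_len(min(100, length(x$sequence)))])),
                    collapse = "/")))
  invisible(x)
}

# Vectorized translation of equal-length inserts (multiple of 3); TAG -> Q
# under amber-to-gln, stops left as '*'.
.translate_inserts <- function(inserts, policy) {
  if (length(inserts) == 0L) return(character(0))
  n_codons <- nchar(inserts[1]) %/% 3L
  code <- Biostrings::GENETIC_CODE
  if (policy$mode == "amber-to-gln") code[.AMBER] <- "Q"
  cols <- lapply(seq_len(n_codons), function(k) {
    unname(code[substr(inserts, 3L * k - 2L, 3L * k)])
  })
  do.call(paste0, cols)
}

#' Simulate sequencing of the naive (pre-screened) library
#'
#' Each read is `flank5 + insert + flank3`, with the insert drawn i.i.d.
#' from the scheme's per-position codon nucleotide distributions (with any
#' synthesis bias applied), so stop-codon-containing clones appear at their
#' natural rate. Base qualities are constant. The returned truth carries the
#' per-read translated peptides (NA for unsuppressed-stop clones), their
#' aggregated counts, and the exact stop-free generating frequencies.
#'
#' @param config A [screen_config()].
#' @return List with components `sample` (a FASTQ sample), and `truth`: a
#'   list with `peptides` (per-read, NA where the clone carries an
#'   unsuppressed stop), `table` (data.frame `peptide`, `count`) and `prior`
#'   (data.frame `peptide`, `f_lib` -- exact stop-free-normalized
#'   frequencies).
#' @export
sample_library <- function(config) {
  stopifnot(inherits(config, "screen_config"))
  scheme <- .biased_scheme(config)
  depth <- config$depth_library
  set.seed(derive_seed(config$seed, "library", 0L))
  cols <- vector("list", scheme$insert_length_nt)
  for (i in seq_along(scheme$positions)) {
    codon <- scheme$positions[[i]]$codon
    for (k in 1:3) {
      p <- codon[[k]]
      cols[[3L * (i - 1L) + k]] <- sample(.BASES, depth, replace = TRUE,
                                          prob = p)
    }
  }
  inserts <- do.call(paste0, cols)
  peptides <- .translate_inserts(inserts, config$policy)
  peptides[grepl("*", peptides, fixed = TRUE)] <- NA_character_
  reads <- paste0(scheme$flank5, inserts, scheme$flank3)
  reads <- .apply_errors(reads, config$error_rate)
  tab <- table(peptides)
  truth_table <- data.frame(peptide = names(tab),
                            count = as.integer(tab))
  prior <- enumerate_peptide_space(scheme, config$policy)
  prior <- data.frame(peptide = prior$peptide,
                      f_lib = prior$probability / sum(prior$probability))
  list(sample = .fastq_sample(sprintf("lib_%07d", seq_len(depth)), reads),
       truth = list(peptides = peptides, table = truth_table, prior = prior))
}

# Closed-form eluate frequencies over the extended clone space.
.eluate_frequencies <- function(config, condition) {
  scheme <- .biased_scheme(config)
  ext <- .extended_space(scheme, config$policy)
  w <- .condition_weights(config, condition, ext$peptide)
  s <- if (config$policy$mode == "amber-to-gln") config$policy$efficiency else 0
  w_clone <- w * s^ext$n_amber
  beta <- config$background
  sel <- ext$prob * w_clone
  total <- sum(sel)
  if (total <= 0) {
    stop("selection retains no mass for condition ", condition, call. = FALSE)
  }
  f_elu <- (1 - beta) * sel / total + beta * ext$prob
  list(ext = ext, f_elu = f_elu)
}

#' Simulate one eluate sample of a single-round screen
#'
#' The eluate peptide distribution is a mixture of proportional-retention
#' selection and nonspecific background carryover:
#' `f_elu(p) = (1 - beta) * f_lib(p) w(p, c) / sum_q f_lib(q) w(q, c) +
#' beta * f_lib(p)`, evaluated over the stop-free clone space with
#' amber-containing clones down-weighted by the suppression efficiency per
#' amber codon. Reads are drawn multinomially at `depth_eluate`; codon usage
#' within each clone class follows the scheme's conditional codon
#' distributions. Replicates use independent sub-seeds derived from
#' `(seed, condition, replicate)`.
#'
#' @param config A [screen_config()].
#' @param condition One of `config$conditions`.
#' @param replicate Replicate index in `1:config$replicates`.
#' @return List with `sample` (FASTQ sample), `truth` (data.frame `peptide`,
#'   `f_lib`, `f_elu`, `E_true = f_elu / f_lib` over the full stop-free
#'   peptide space), `condition`, `replicate`.
#' @export
sample_eluate <- function(config, condition, replicate = 1L) {
  stopifnot(inherits(config, "screen_config"))
  if (!condition %in% config$conditions) {
    stop("unknown condition '", condition, "'", call. = FALSE)
  }
  if (replicate < 1L || replicate > config$replicates) {
    stop("replicate out of range", call. = FALSE)
  }
  ef <- .eluate_frequencies(config, condition)
  ext <- ef$ext
  depth <- config$depth_eluate

  set.seed(derive_seed(config$seed, condition, replicate))
  counts <- as.integer(stats::rmultinom(1L, depth, ef$f_elu))
  idx <- rep.int(seq_along(counts), counts)
  idx <- sample(idx)  # interleave clone classes in read order

  n_pos <- ncol(ext$symbol_mat)
  cols <- vector("list", n_pos)
  for (j in seq_len(n_pos)) {
    syms <- ext$symbol_mat[idx, j]
    cod <- character(length(idx))
    pp <- ext$per_pos[[j]]
    for (s in unique(syms)) {
      sel <- syms == s
      pv <- pp$codons[[s]]
      cod[sel] <- sample(names(pv), sum(sel), replace = TRUE, prob = pv)
    }
    cols[[j]] <- cod
  }
  inserts <- do.call(paste0, cols)
  scheme <- .biased_scheme(config)
  reads <- paste0(scheme$flank5, inserts, scheme$flank3)
  reads <- .apply_errors(reads, config$error_rate)

  f_lib_pep <- rowsum(ext$prob, ext$peptide)
  f_elu_pep <- rowsum(ef$f_elu, ext$peptide)
  truth <- data.frame(peptide = rownames(f_lib_pep),
                      f_lib = as.numeric(f_lib_pep),
                      f_elu = as.numeric(f_elu_pep))
  truth$E_true <- truth$f_elu / truth$f_lib
  rownames(truth) <- NULL

  tag <- gsub("[^A-Za-z0-9._-]", "-", condition)
  list(sample = .fastq_sample(
         sprintf("%s_r%d_%07d", tag, replicate, seq_along(idx)), reads),
       truth = truth, condition = condition, replicate = as.integer(replicate))
}

#' Write a FASTQ sample to disk
#'
#' Standard 4-line records with constant quality; gzipped when `path` ends
#' in `.gz`.
#'
#' @param x A FASTQ sample as produced by the simulator.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(x, path) {
  stopifnot(inherits(x, "fastq_sample"))
  lines <- as.vector(rbind(paste0("@", x$id), x$sequence, "+", x$quality))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a FASTQ file into a sample object
#'
#' @param path FASTQ path (plain or gzipped).
#' @return A FASTQ sample (ids and sequences; qualities are not retained --
#'   downstream processing ignores them).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  .fastq_sample(names(x), unname(as.character(x)))
}

#' Write a complete simulated screen to a directory
#'
#' Emits the library FASTQ, one FASTQ per condition x replicate, the
#' matching truth tables as TSV, and the configuration echoed as YAML.
#' File names are deterministic; a rerun with the same config is
#' byte-identical.
#'
#' @param config A [screen_config()].
#' @param outdir Output directory (created if missing).
#' @return Named character vector of written file paths, invisibly.
#' @export
write_fixture_bundle <- function(config, outdir) {
  stopifnot(inherits(config, "screen_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()

  lib <- sample_library(config)
  p <- file.path(outdir, "library.fastq")
  write_fastq(lib$sample, p)
  paths["library"] <- p
  p <- file.path(outdir, "library_truth.tsv")
  utils::write.table(lib$truth$table, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths["library_truth"] <- p

  for (cond in config$conditions) {
    tag <- gsub("[^A-Za-z0-9._-]", "-", cond)
    for (r in seq_len(config$replicates)) {
      elu <- sample_eluate(config, cond, r)
      p <- file.path(outdir, sprintf("eluate_%s_rep%d.fastq", tag, r))
      write_fastq(elu$sample, p)
      paths[sprintf("eluate_%s_rep%d", tag, r)] <- p
      truth <- elu$truth
      truth$condition <- cond
      truth$replicate <- r
      p <- file.path(outdir, sprintf("truth_%s_rep%d.tsv", tag, r))
      utils::write.table(
        truth[, c("peptide", "condition", "replicate",
                  "f_lib", "f_elu", "E_true")],
        p, sep = "\t", quote = FALSE, row.names = FALSE)
      paths[sprintf("truth_%s_rep%d", tag, r)] <- p
    }
  }

  p <- file.path(outdir, "config.yaml")
  schemefile <- file.path(outdir, "scheme.yaml")
  write_scheme(config$scheme, schemefile)
  yaml::write_yaml(list(
    scheme = "scheme.yaml",
    policy = list(mode = config$policy$mode,
                  efficiency = config$policy$efficiency),
    conditions = as.list(config$conditions),
    replicates = config$replicates,
    depth_library = config$depth_library,
    depth_eluate = config$depth_eluate,
    background = config$background,
    error_rate = config$error_rate,
    seed = config$seed), p)
  paths["config"] <- p
  paths["scheme"] <- schemefile
  invisible(paths)
}
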