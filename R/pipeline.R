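# End-to-end pipeline: count every sample, compute enrichment per
# condition/replicate, replicate concordance, hit lists and consensus, and
# write all tables with a config hash.

# 32-bit FNV-1a hash of a string, hex-encoded; used to stamp outputs so a
# table can be traced to the configuration that produced it.
.config_hash <- function(x) {
  h <- 2166136261
  for (v in utf8ToInt(x)) {
    h <- bitwXor(as.integer(h %% 2^31), v)  # keep in integer range
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

.pipeline_stop <- function(msg, class) {
  stop(structure(class = c(class, "pipeline_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Pipeline configuration
#'
#' @param scheme A [library_scheme()] or path to a scheme YAML.
#' @param samples data.frame with columns `label`, `path` (FASTQ), `role`
#'   (`"library"` or `"eluate"`), `condition` (NA for the library) and
#'   `replicate` (integer; NA for the library). Exactly one library sample
#'   is required, and every eluate needs a condition.
#' @param policy A [suppression_policy()].
#' @param anchor_len Flank anchor length for insert extraction.
#' @param pseudocount Pseudocount for per-peptide factors.
#' @param min_factor Hit-calling threshold.
#' @param outdir Output directory.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(scheme, samples, policy = suppression_policy(),
                            anchor_len = 12L, pseudocount = 0.5,
                            min_factor = 1.0, outdir = "pipeline_out") {
  if (is.character(scheme)) scheme <- read_scheme(scheme)
  .validate_scheme(scheme)
  need <- c("label", "path", "role", "condition", "replicate")
  if (!is.data.frame(samples) || !all(need %in% names(samples))) {
    .pipeline_stop(paste("samples must be a data.frame with columns",
                         paste(need, collapse = ", ")),
                   "pipeline_config_error")
  }
  if (sum(samples$role == "library") != 1L) {
    .pipeline_stop("exactly one sample must have role 'library'",
                   "pipeline_config_error")
  }
  elu <- samples[samples$role == "eluate", , drop = FALSE]
  if (nrow(elu) == 0L || any(is.na(elu$condition))) {
    .pipeline_stop("every eluate sample needs a condition",
                   "pipeline_config_error")
  }
  missing <- !file.exists(samples$path)
  if (any(missing)) {
    .pipeline_stop(paste("missing input file(s):",
                         paste(samples$path[missing], collapse = ", ")),
                   "pipeline_input_error")
  }
  structure(list(scheme = scheme, samples = samples, policy = policy,
                 anchor_len = as.integer(anchor_len),
                 pseudocount = pseudocount, min_factor = min_factor,
                 outdir = outdir),
            class = "pipeline_config")
}

#' Run the full counting/enrichment/ranking pipeline
#'
#' Counts every sample, computes per-peptide and residue-level enrichment of
#' each eluate against the library, joins replicate pairs into concordance
#' tables, calls hits per condition, derives the cross-condition consensus
#' peptide, and writes every table as TSV (stamped with the configuration
#' hash) plus a machine-readable `summary.yaml` and a run log. Idempotent
#' for fixed inputs.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages (default `FALSE`).
#' @return Invisibly, a summary list: per-sample totals, per-condition
#'   concordance (`n`, `pearson_log10`), top hit per condition, the
#'   consensus peptide, and the config hash.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  hash <- .config_hash(paste(
    utils::capture.output(utils::str(config$samples)),
    config$anchor_len, config$pseudocount, config$min_factor,
    config$policy$mode, collapse = "\n"))
  stamp <- paste0("panenrich config ", hash)

  samples <- config$samples
  tables <- list()
  for (i in seq_len(nrow(samples))) {
    lab <- samples$label[i]
    say("counting sample ", lab)
    tables[[lab]] <- count_sample(samples$path[i], config$scheme,
                                  config$policy, config$anchor_len,
                                  sample = lab)
    write_count_table(tables[[lab]],
                      file.path(config$outdir,
                                paste0("counts_", lab, ".tsv")),
                      file.path(config$outdir,
                                paste0("rejects_", lab, ".tsv")),
                      header_comment = stamp)
  }
  lib_lab <- samples$label[samples$role == "library"]
  lib_tab <- tables[[lib_lab]]
  lib_pf <- position_frequencies(lib_tab, config$scheme)

  elu <- samples[samples$role == "eluate", , drop = FALSE]
  residue_all <- list()
  summary <- list(config_hash = hash,
                  samples = lapply(tables, function(t) t$totals),
                  conditions = list())
  for (cond in unique(elu$condition)) {
    rows <- elu[elu$condition == cond, , drop = FALSE]
    pe <- list(); res_cond <- list()
    for (i in seq_len(nrow(rows))) {
      lab <- rows$label[i]
      pe[[lab]] <- peptide_enrichment(tables[[lab]], lib_tab,
                                      config$pseudocount)
      .write_tsv(as.data.frame(pe[[lab]]),
                 file.path(config$outdir,
                           paste0("peptide_enrichment_", lab, ".tsv")),
                 stamp)
      re <- residue_enrichment(position_frequencies(tables[[lab]],
                                                    config$scheme),
                               lib_pf)
      re$condition <- cond
      re$replicate <- rows$replicate[i]
      res_cond[[lab]] <- re
      .write_tsv(re, file.path(config$outdir,
                               paste0("residue_enrichment_", lab, ".tsv")),
                 stamp)
    }
    residue_all[[cond]] <- do.call(rbind, res_cond)
    cond_summary <- list()
    if (nrow(rows) >= 2L) {
      if (nrow(rows) != 2L) {
        .pipeline_stop(paste("condition", cond, "has", nrow(rows),
                             "eluates; replicate concordance needs exactly 2"),
                       "pipeline_replicate_error")
      }
      conc <- replicate_concordance(pe[[rows$label[1]]], pe[[rows$label[2]]])
      hits <- call_hits(conc, config$min_factor)
      tag <- gsub("[^A-Za-z0-9._-]", "-", cond)
      .write_tsv(conc$table,
                 file.path(config$outdir,
                           paste0("concordance_", tag, ".tsv")), stamp)
      .write_tsv(data.frame(condition = cond, n = conc$n,
                            pearson_log10 = conc$pearson_log10),
                 file.path(config$outdir,
                           paste0("concordance_summary_", tag, ".tsv")),
                 stamp)
      .write_tsv(as.data.frame(hits),
                 file.path(config$outdir, paste0("hits_", tag, ".tsv")),
                 stamp)
      cond_summary$n <- conc$n
      cond_summary$pearson_log10 <- conc$pearson_log10
      if (nrow(hits) > 0L) {
        cond_summary$top_hit <- hits$peptide[1]
        cond_summary$top_score <- hits$score[1]
      }
      say(sprintf("condition %s: N = %d, r(log10) = %.3f, %d hits",
                  cond, conc$n, conc$pearson_log10, nrow(hits)))
    }
    summary$conditions[[cond]] <- cond_summary
  }

  residue_stacked <- do.call(rbind, residue_all)
  rownames(residue_stacked) <- NULL
  .write_tsv(residue_stacked,
             file.path(config$outdir, "residue_enrichment_all.tsv"), stamp)
  consensus <- consensus_peptide(residue_stacked, config$scheme)
  summary$consensus <- consensus
  say("consensus peptide: ", consensus)

  yaml::write_yaml(summary, file.path(config$outdir, "summary.yaml"))
  writeLines(c(paste0("# ", stamp),
               paste0("panenrich ",
                      as.character(utils::packageVersion("panenrich"))),
               paste0("R ", R.version.string),
               paste0("samples: ",
                      paste(samples$label, collapse = ", ")),
               paste0("anchor_len: ", config$anchor_len),
               paste0("pseudocount: ", config$pseudocount),
               paste0("min_factor: ", config$min_factor)),
             file.path(config$outdir, "run_log.txt"))
  invisible(summary)
}

#' Expected versus observed per-position residue frequencies
#'
#' Pairs the observed per-position residue frequencies of a counted naive
#' library with the scheme's analytic expectations and flags residues whose
#' observed/expected ratio deviates by more than `ratio_threshold` in either
#' direction -- the diagnostic that exposes synthesis biases such as a
#' Phe:Tyr skew at Tyr/Phe-degenerate positions.
#'
#' @param library_counts A `peptide_count_table` of the naive library.
#' @param scheme A [library_scheme()].
#' @param policy A [suppression_policy()].
#' @param ratio_threshold Flag when `observed/expected > ratio_threshold`
#'   or `< 1/ratio_threshold` (default 1.5). Residues with expected
#'   frequency below `min_expected` are not flagged (ratios of rare
#'   residues are sampling noise).
#' @param min_expected Minimum expected frequency for flagging (default
#'   0.01).
#' @return data.frame with columns `position`, `residue`, `observed`,
#'   `expected`, `ratio`, `flag`. Expectations are renormalized over
#'   stop-free mass to be comparable with observed (stop-free) reads.
#' @export
expected_vs_observed_report <- function(library_counts, scheme,
                                        policy = suppression_policy(),
                                        ratio_threshold = 1.5,
                                        min_expected = 0.01) {
  obs <- position_frequencies(library_counts, scheme)
  names(obs)[names(obs) == "frequency"] <- "observed"
  exp_tab <- expected_frequency_table(scheme, policy, renormalize = TRUE)
  names(exp_tab)[names(exp_tab) == "expected_frequency"] <- "expected"
  out <- merge(exp_tab, obs, by = c("position", "residue"), all = TRUE)
  out$observed[is.na(out$observed)] <- 0
  out$expected[is.na(out$expected)] <- 0
  out$ratio <- ifelse(out$expected > 0, out$observed / out$expected, NA)
  out$flag <- !is.na(out$ratio) & out$expected >= min_expected &
    (out$ratio > ratio_threshold | out$ratio < 1 / ratio_threshold)
  out <- out[order(out$position, out$residue, method = "radix"), ]
  rownames(out) <- NULL
  out
}
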