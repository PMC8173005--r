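test_that("position frequencies are exact fractions of accepted reads", {
  sch <- tiny_scheme()
  ct <- peptide_count_table(c(GSY = 10L))
  pf <- position_frequencies(ct, sch)
  expect_equal(pf$frequency[pf$position == 2], 1)
  expect_identical(pf$residue[pf$position == 2], "S")

  ct2 <- peptide_count_table(c(GSY = 3L, GHY = 1L))
  pf2 <- position_frequencies(ct2, sch)
  expect_equal(pf2$frequency[pf2$position == 2 & pf2$residue == "S"], 0.75)
  expect_equal(pf2$frequency[pf2$position == 2 & pf2$residue == "H"], 0.25)
  for (j in 1:3) {
    expect_equal(sum(pf2$frequency[pf2$position == j]), 1, tolerance = 1e-9)
  }
  empty <- peptide_count_table(c(GSY = 1L))
  empty$counts <- empty$counts[0]
  expect_error(position_frequencies(empty, sch), "empty sample")
})

test_that("residue enrichment is the frequency ratio against the library", {
  sch <- tiny_scheme()
  lib <- position_frequencies(peptide_count_table(
    c(GSY = 5L, GHY = 5L, GSF = 10L)), sch)
  re_id <- residue_enrichment(lib, lib)
  expect_equal(re_id$enrichment, rep(1, nrow(re_id)))
  elu <- position_frequencies(peptide_count_table(
    c(GSY = 4L, GHY = 12L, GSF = 4L)), sch)
  re <- residue_enrichment(elu, lib)
  # H at position 2: 0.6 eluate / 0.25 library
  expect_equal(re$enrichment[re$position == 2 & re$residue == "H"], 2.4)
  # residues absent from the library are not emitted
  expect_false(any(re$residue == "W"))
})

test_that("residue factors agree with brute-force peptide marginalization", {
  sch <- pair_scheme()
  set.seed(31)
  es <- enumerate_peptide_space(sch)
  lib_ct <- counts_from_freqs(es$peptide, es$probability, 5e4, "lib")
  w <- stats::rlnorm(nrow(es), 0, 1)
  f_elu <- es$probability * w / sum(es$probability * w)
  elu_ct <- counts_from_freqs(es$peptide, f_elu, 2e4, "elu")
  re <- residue_enrichment(position_frequencies(elu_ct, sch),
                           position_frequencies(lib_ct, sch))
  # oracle: marginalize raw peptide counts by residue at each position
  for (j in 1:2) {
    for (res in unique(re$residue[re$position == j])) {
      fl <- sum(lib_ct$counts[substr(names(lib_ct$counts), j, j) == res]) /
        sum(lib_ct$counts)
      fe <- sum(elu_ct$counts[substr(names(elu_ct$counts), j, j) == res]) /
        sum(elu_ct$counts)
      expect_equal(re$enrichment[re$position == j & re$residue == res],
                   fe / fl, tolerance = 1e-9)
    }
  }
})

test_that("peptide enrichment identities hold at pseudocount 0", {
  ct <- peptide_count_table(c(AAA = 10L, BBB = 30L, CCC = 5L))
  pe <- peptide_enrichment(ct, ct, pseudocount = 0)
  expect_equal(pe$enrichment, rep(1, 3))
  # scale invariance: multiplying all counts leaves factors unchanged
  elu <- peptide_count_table(c(AAA = 20L, BBB = 10L, CCC = 15L))
  pe1 <- peptide_enrichment(elu, ct, pseudocount = 0)
  scale7 <- function(x) peptide_count_table(x$counts * 7L, x$sample)
  pe7 <- peptide_enrichment(scale7(elu), scale7(ct), pseudocount = 0)
  expect_equal(pe1$enrichment, pe7$enrichment, tolerance = 1e-12)
})

test_that("peptide enrichment arithmetic and pseudocount bookkeeping", {
  elu <- peptide_count_table(c(P1 = 20L, P2 = 80L))
  lib <- peptide_count_table(c(P1 = 10L, P2 = 490L, P3 = 500L))
  pe <- peptide_enrichment(elu, lib, pseudocount = 0)
  expect_equal(pe$enrichment[pe$peptide == "P1"], 0.2 / 0.01)
  expect_identical(attr(pe, "v_union"), 3L)
  # peptide absent from the library: skipped at pseudocount 0, kept otherwise
  elu2 <- peptide_count_table(c(P1 = 20L, PX = 5L))
  expect_warning(pe0 <- peptide_enrichment(elu2, lib, pseudocount = 0),
                 "absent")
  expect_false("PX" %in% pe0$peptide)
  pe5 <- peptide_enrichment(elu2, lib, pseudocount = 0.5)
  expect_true("PX" %in% pe5$peptide)
  expect_identical(attr(pe5, "pseudocount"), 0.5)
  ex <- pe5[pe5$peptide == "PX", ]
  v <- attr(pe5, "v_union")
  expect_equal(ex$enrichment,
               ((5 + 0.5) / (25 + 0.5 * v)) / ((0 + 0.5) / (1000 + 0.5 * v)),
               tolerance = 1e-12)
  expect_error(peptide_enrichment(elu, lib, pseudocount = -1), "nonnegative")
})

test_that("replicate concordance joins on eluate detection and correlates logs", {
  lib <- peptide_count_table(c(P1 = 100L, P2 = 100L, P3 = 100L, P4 = 700L))
  eluA <- peptide_count_table(c(P1 = 10L, P2 = 40L, P3 = 160L))
  peA <- peptide_enrichment(eluA, lib)
  conc_same <- replicate_concordance(peA, peA)
  expect_identical(conc_same$n, 3L)
  expect_equal(conc_same$pearson_log10, 1, tolerance = 1e-12)

  # union rule: P4 detected only in replicate B still enters, with A's
  # zero-count factor filled in
  eluB <- peptide_count_table(c(P1 = 12L, P2 = 35L, P4 = 5L))
  peB <- peptide_enrichment(eluB, lib)
  conc <- replicate_concordance(peA, peB)
  expect_identical(conc$n, 4L)
  expect_identical(conc$table$count_eluate_b[conc$table$peptide == "P3"], 0L)
  expect_true(all(is.finite(conc$table$enrichment_a)))

  # fewer than 3 peptides: undefined correlation
  small <- peptide_enrichment(peptide_count_table(c(P1 = 5L)), lib)
  expect_true(is.na(replicate_concordance(small, small)$pearson_log10))

  peA0 <- peptide_enrichment(eluA, lib, pseudocount = 0)
  expect_error(replicate_concordance(peA, peA0), "identical pseudocounts")
})

test_that("shuffled replicate factors decorrelate (permutation null)", {
  sch <- pair_scheme()
  set.seed(41)
  es <- enumerate_peptide_space(sch)
  n_pep <- nrow(es)
  lib_ct <- counts_from_freqs(es$peptide, es$probability, 2e5, "lib")
  w <- stats::rlnorm(n_pep, 0, 2)
  f_elu <- es$probability * w / sum(es$probability * w)
  peA <- peptide_enrichment(counts_from_freqs(es$peptide, f_elu, 2e4, "a"),
                            lib_ct)
  peB <- peA
  perm <- sample(nrow(peB))
  peB$count_eluate <- peB$count_eluate[perm]
  peB$enrichment <- peB$enrichment[perm]
  conc <- replicate_concordance(peA, peB)
  expect_gte(conc$n, 300)
  expect_lt(abs(conc$pearson_log10), 0.2)
})

test_that("hit calling requires enrichment in both replicates and ranks stably", {
  tab <- data.frame(peptide = c("PA", "PB", "PC", "PD", "PE"),
                    enrichment_a = c(2.0, 4.0, 3.0, 0.9, 9.0),
                    enrichment_b = c(0.5, 9.0, 3.0, 1.2, 4.0))
  hits <- call_hits(tab, min_factor = 1)
  # PA fails one replicate, PD fails the other
  expect_identical(hits$peptide, c("PB", "PE", "PC"))
  expect_equal(hits$score[1], 6.0)
  expect_identical(hits$rank, 1:3)
  # ties break lexicographically; input order is irrelevant
  tie <- data.frame(peptide = c("PZ", "PY"),
                    enrichment_a = c(2, 4), enrichment_b = c(8, 4))
  expect_identical(call_hits(tie)$peptide, c("PY", "PZ"))
  expect_identical(call_hits(tie[2:1, ])$peptide, c("PY", "PZ"))
  expect_identical(nrow(call_hits(tab, top = 2)), 2L)
})

test_that("consensus takes the argmax residue per randomized position", {
  sch <- igg_focused_scheme()
  # all factors equal: lexicographically first residue at each randomized
  # position, fixed residues retained
  grid <- expand.grid(position = c(2, 3, 5, 6, 7, 9),
                      residue = c("A", "C", "V", "Y", "F"),
                      stringsAsFactors = FALSE)
  grid$enrichment <- 1
  expect_identical(consensus_peptide(grid, sch), "GAAWAAAWA")

  grid2 <- grid
  grid2$enrichment[grid2$position == 7 & grid2$residue == "V"] <- 3.6
  grid2$enrichment[grid2$position == 7 & grid2$residue == "C"] <- 1.9
  expect_identical(substr(consensus_peptide(grid2, sch), 7, 7), "V")

  # factors averaged across conditions/replicates before the argmax
  two <- rbind(cbind(grid, condition = "pH2.2"),
               cbind(grid, condition = "pH3.6"))
  two$enrichment[two$position == 2 & two$residue == "C" &
                   two$condition == "pH2.2"] <- 9
  expect_identical(substr(consensus_peptide(two, sch), 2, 2), "C")
  expect_identical(substr(consensus_peptide(two, sch,
                                            conditions = "pH3.6"), 2, 2), "A")
  expect_error(consensus_peptide(grid[grid$position != 6, ], sch),
               "position 6")
})

test_that("recovered factors track closed-form truth on direct multinomials", {
  # estimator-level parameter recovery: two NNK positions (400 peptides),
  # 20 planted binders, no background; counts drawn straight from the
  # closed-form frequencies
  sch <- pair_scheme()
  pol <- suppression_policy()
  set.seed(19)
  es <- enumerate_peptide_space(sch, pol)
  f_lib <- es$probability / sum(es$probability)
  planted <- es$peptide[seq(10, 200, by = 10)]
  w <- stats::setNames(rep(1, nrow(es)), es$peptide)
  w[planted] <- exp(seq(log(5), log(50), length.out = length(planted)))
  f_elu <- f_lib * w / sum(f_lib * w)
  e_true <- f_elu / f_lib

  n_lib <- 5e5; n_elu <- 2e4
  lib_ct <- counts_from_freqs(es$peptide, f_lib, n_lib, "lib")
  elu_ct <- counts_from_freqs(es$peptide, f_elu, n_elu, "elu")
  pe <- suppressWarnings(peptide_enrichment(elu_ct, lib_ct, pseudocount = 0))
  keep <- es$peptide[f_elu * n_elu >= 50]
  i <- match(keep, pe$peptide)
  rel_err <- abs(pe$enrichment[i] / e_true[match(keep, es$peptide)] - 1)
  expect_lt(stats::median(rel_err, na.rm = TRUE), 0.10)
})
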