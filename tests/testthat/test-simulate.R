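tiny_config <- function(...) {
  args <- list(scheme = tiny_scheme(), conditions = c("pH3.6", "pH9.0"),
               replicates = 2L, depth_library = 3000L, depth_eluate = 800L,
               background = 0.1, seed = 5)
  over <- list(...)
  args[names(over)] <- over
  do.call(screen_config, args)
}

test_that("simulated reads have the designed layout and constant quality", {
  cfg <- tiny_config()
  lib <- sample_library(cfg)
  expect_length(lib$sample$sequence, 3000)
  expect_true(all(nchar(lib$sample$sequence) ==
                    nchar(cfg$scheme$flank5) + 9 + nchar(cfg$scheme$flank3)))
  expect_true(all(startsWith(lib$sample$sequence, cfg$scheme$flank5)))
  expect_true(all(endsWith(lib$sample$sequence, cfg$scheme$flank3)))
  expect_true(all(lib$sample$quality == strrep("I", 12 + 9 + 12)))

  one <- screen_config(scheme = tiny_scheme(), depth_library = 1L, seed = 5)
  expect_length(sample_library(one)$sample$sequence, 1)
})

test_that("library truth carries exact generating frequencies", {
  cfg <- tiny_config()
  lib <- sample_library(cfg)
  prior <- lib$truth$prior
  expect_equal(sum(prior$f_lib), 1, tolerance = 1e-12)
  es <- enumerate_peptide_space(cfg$scheme, cfg$policy)
  expect_identical(prior$peptide, es$peptide)
  expect_equal(prior$f_lib, es$probability / sum(es$probability),
               tolerance = 1e-12)
  # per-read truth is consistent with its aggregated table
  tab <- table(lib$truth$peptides[!is.na(lib$truth$peptides)])
  expect_identical(lib$truth$table$count[match(names(tab),
                                               lib$truth$table$peptide)],
                   as.integer(tab))
})

test_that("library sampling matches analytic expectations at depth", {
  cfg <- screen_config(scheme = tiny_scheme(), depth_library = 20000L,
                       seed = 9)
  lib <- sample_library(cfg)
  ct <- count_sample(lib$sample, cfg$scheme, cfg$policy)
  pf <- position_frequencies(ct, cfg$scheme)
  ef <- expected_position_frequencies(cfg$scheme, cfg$policy,
                                      renormalize = TRUE)
  n <- sum(ct$counts)
  for (j in seq_along(ef)) {
    for (res in names(ef[[j]])[ef[[j]] > 0]) {
      p <- ef[[j]][[res]]
      obs <- pf$frequency[pf$position == j & pf$residue == res]
      if (length(obs) == 0) obs <- 0
      expect_lt(abs(obs - p), 3 * sqrt(p * (1 - p) / n) + 1e-12)
    }
  }
})

test_that("synthesis bias skews the sampled nucleotide pool", {
  # Phe:Tyr 2:1 at the TWT position: T at nt2 twice as likely as A
  biased <- parse_degenerate_codon(list(c(0, 0, 0, 1), c(1, 0, 0, 2),
                                        c(0, 0, 0, 1)))
  cfg <- screen_config(scheme = tiny_scheme(), depth_library = 30000L,
                       synthesis_bias = list("3" = biased), seed = 13)
  lib <- sample_library(cfg)
  ct <- count_sample(lib$sample, cfg$scheme, cfg$policy)
  pf <- position_frequencies(ct, cfg$scheme)
  ratio <- pf$frequency[pf$position == 3 & pf$residue == "F"] /
    pf$frequency[pf$position == 3 & pf$residue == "Y"]
  expect_equal(ratio, 2, tolerance = 0.1)
  # the returned generating frequencies reflect the bias exactly
  fY <- sum(lib$truth$prior$f_lib[substr(lib$truth$prior$peptide, 3, 3) == "Y"])
  expect_equal(fY, 1 / 3, tolerance = 1e-12)
})

test_that("eluate truth follows the selection-plus-background closed form", {
  # uniform weights: selection term reduces to the library, E_true = 1
  # (policy "none": under amber suppression the efficiency penalty itself
  # reweights amber-encoded clones, so exact unity needs no amber mass)
  cfg <- tiny_config(policy = suppression_policy("none"))
  elu <- sample_eluate(cfg, "pH3.6", 1)
  expect_equal(sum(elu$truth$f_elu), 1, tolerance = 1e-9)
  expect_equal(elu$truth$E_true, rep(1, nrow(elu$truth)), tolerance = 1e-9)

  # pure background: eluate distribution identical to the library
  pl <- data.frame(peptide = "GAF", weight = 100)
  cfg_b1 <- tiny_config(background = 1, weights = weight_model(planted = pl),
                        policy = suppression_policy("none"))
  elu_b1 <- sample_eluate(cfg_b1, "pH3.6", 1)
  expect_equal(elu_b1$truth$f_elu, elu_b1$truth$f_lib, tolerance = 1e-12)

  # single planted peptide, beta = 0: E(planted) = w / (f_lib-weighted mean w)
  cfg_p <- screen_config(scheme = tiny_scheme(), conditions = "pH3.6",
                         depth_library = 1000L, depth_eluate = 500L,
                         background = 0, policy = suppression_policy("none"),
                         weights = weight_model(planted = pl), seed = 5)
  elu_p <- sample_eluate(cfg_p, "pH3.6", 1)
  tr <- elu_p$truth
  wbar <- sum(tr$f_lib * ifelse(tr$peptide == "GAF", 100, 1))
  expect_equal(tr$E_true[tr$peptide == "GAF"], 100 / wbar, tolerance = 1e-9)
  expect_equal(tr$E_true[tr$peptide != "GAF"][1], 1 / wbar, tolerance = 1e-9)
})

test_that("amber-containing clones are down-weighted in selection only", {
  cfg <- screen_config(scheme = tiny_scheme(), conditions = "sel",
                       background = 0, depth_library = 1000L,
                       depth_eluate = 500L,
                       policy = suppression_policy("amber-to-gln", 0.5),
                       seed = 5)
  tr <- sample_eluate(cfg, "sel", 1)$truth
  # Gln at the NNK position is part-amber-encoded: depleted by selection
  gq <- tr[substr(tr$peptide, 2, 2) == "Q", ]
  ga <- tr[substr(tr$peptide, 2, 2) == "A", ]
  expect_true(all(gq$E_true < ga$E_true))
  # but the library prior itself is unaffected by the efficiency
  expect_equal(sum(tr$f_lib), 1, tolerance = 1e-12)
  cfg2 <- cfg
  cfg2$policy <- suppression_policy("amber-to-gln", 0.9)
  tr2 <- sample_eluate(cfg2, "sel", 1)$truth
  expect_equal(tr2$f_lib, tr$f_lib, tolerance = 1e-12)
  expect_true(all(tr2$E_true[substr(tr2$peptide, 2, 2) == "Q"] > gq$E_true))
})

test_that("unknown conditions and bad configs are rejected", {
  cfg <- tiny_config()
  expect_error(sample_eluate(cfg, "pH7.4", 1), "unknown condition")
  expect_error(sample_eluate(cfg, "pH3.6", 3), "replicate")
  expect_error(screen_config(scheme = tiny_scheme(), background = 1.2))
  expect_error(weight_model(planted = data.frame(x = 1)), "peptide")
  expect_error(
    sample_eluate(screen_config(
      scheme = tiny_scheme(), conditions = "c",
      weights = weight_model(
        planted = data.frame(peptide = "WWW", weight = 2)), seed = 1),
      "c", 1),
    "not in the scheme")
})

test_that("fixture bundles are deterministic under the seed", {
  cfg <- tiny_config()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_fixture_bundle(cfg, d1)
  p2 <- write_fixture_bundle(cfg, d2)
  # 1 library + 2 conditions x 2 replicates
  expect_length(grep("\\.fastq$", p1), 5L)
  for (nm in names(p1)) {
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]),
                     label = paste("bundle file", nm))
  }
  # different seed: different reads, identical truth marginals
  cfg3 <- tiny_config(seed = 99L)
  d3 <- withr::local_tempdir()
  p3 <- write_fixture_bundle(cfg3, d3)
  expect_false(identical(readLines(p1[["library"]]),
                         readLines(p3[["library"]])))
  t1 <- read_tsv(p1[["truth_pH3.6_rep1"]])
  t3 <- read_tsv(p3[["truth_pH3.6_rep1"]])
  expect_equal(t1$f_elu, t3$f_elu, tolerance = 1e-12)
  expect_equal(t1$E_true, t3$E_true, tolerance = 1e-12)
})

test_that("sub-seed derivation separates streams deterministically", {
  expect_identical(derive_seed(7, "pH3.6", 1), derive_seed(7, "pH3.6", 1))
  expect_false(derive_seed(7, "pH3.6", 1) == derive_seed(7, "pH3.6", 2))
  expect_false(derive_seed(7, "pH3.6", 1) == derive_seed(7, "pH9.0", 1))
  expect_false(derive_seed(7, "library", 0) == derive_seed(8, "library", 0))
})

test_that("read errors perturb reads at the configured rate", {
  cfg0 <- tiny_config()
  cfg1 <- tiny_config(error_rate = 0.02)
  r0 <- sample_library(cfg0)$sample$sequence
  r1 <- sample_library(cfg1)$sample$sequence
  # same seed: identical before errors, so differences are the errors
  frac <- mean(r0 != r1)
  expect_gt(frac, 0.4)  # P(read untouched) = 0.98^63 ~ 0.28
  ct <- count_sample(r1, cfg1$scheme, cfg1$policy)
  expect_gt(sum(ct$totals$rejected[c("no_flank", "wrong_length")]), 0)
})
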