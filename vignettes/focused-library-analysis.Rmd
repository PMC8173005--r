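---
title: "Models and methods: focused phage-display library analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: focused phage-display library analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panenrich)
```

# The problem

A focused (secondary) phage-display library probes the sequence
neighbourhood of a lead peptide: residues essential for binding are kept
fixed, tolerant ones are randomized. After a *single* round of affinity
selection, deep sequencing of the pre-screened library and of the eluates
replaces iterative panning: a binder reveals itself by the ratio of its
frequency after selection to its frequency before,

$$E(p) = \frac{f_\mathrm{elu}(p)}{f_\mathrm{lib}(p)}.$$

Because one selection round retains substantial nonspecifically bound
phage, hits are only trusted when they are enriched in **two parallel
independent screens** — replicate concordance is the background filter.
`panenrich` implements the three layers of this design: the exact codon
mathematics of the library, a generative simulator of the screen, and the
counting/enrichment/ranking analysis.

# Codon models

A degenerate codon is three independent probability vectors over
A/C/G/T. IUPAC triplets ("NNK", "TWT", ...) put uniform weight on the
allowed bases; soft randomization (doping) uses explicit mix ratios. The
amino-acid distribution of a codon is the exact sum over all 64 codons of
the product of marginals, accumulated by residue under the standard
genetic code:

```{r}
soft <- parse_degenerate_codon(list(c(10, 10, 70, 10),
                                    c(70, 10, 10, 10),
                                    c(10, 10, 10, 70)))
round(100 * codon_aa_distribution(soft)[c("D", "E", "G", "N", "M", "W")], 1)
```

Two conventions matter and are deliberate:

* **No stop renormalization.** Distributions are reported over the full
  codon mass including residual stop probability. This is what makes the
  doped codon's aspartate expectation come out at exactly
  $0.7^3 + 0.7^2 \cdot 0.1 = 39.2\%$; renormalizing over stop-free mass
  would inflate every entry by ~0.8% relative. A `renormalize = TRUE`
  option exists for comparing against observed (necessarily stop-free)
  read frequencies, and is what `expected_vs_observed_report()` uses.
* **Amber policy.** In supE hosts (E. coli TG1) the amber codon TAG is
  read through as Gln. Under the default `amber-to-gln` policy the TAG
  mass is *moved* to Gln in analytic distributions — a recoding, not a
  partial-efficiency scaling. The suppression efficiency (default 0.5,
  the midpoint of the 41–61% literature range for TG1) is exclusively a
  *selection weight* in the simulator: a clone must read through every
  amber codon to display its peptide, so its retention is multiplied by
  $s$ per amber codon, while its abundance in the naive library is
  unaffected. This asymmetry reproduces the known artefact that
  Gln enrichment at NNK positions is partly an amber artefact and its
  frequency overestimated when suppression is incomplete.

Diversity is counted over *distinct stop-free peptides* reachable with
nonzero probability, with amber collapsed into Gln before counting.
Positions are independent, so the count is a product of per-position
residue counts — exact in integer-valued doubles far beyond the 12
randomized positions the package guards for:

```{r}
scheme <- igg_focused_scheme()
peptide_space_size(scheme)
```

# The screen simulator

The simulator exists so that every downstream stage is testable against
closed-form truth without any sequencing data. Its layers:

* **Naive library.** Each read is `flank5 + insert + flank3`; insert
  nucleotides are drawn i.i.d. from the per-position codon vectors, so
  stop-containing clones appear at their natural rate (0.8% for the
  built-in scheme) and are exercised by the rejection logic. Optional
  `synthesis_bias` swaps in replacement codon vectors, emulating pool
  synthesis artefacts such as a 2:1 Phe:Tyr skew at TWT positions.
* **Selection.** One-pass proportional retention: eluate frequencies are
  $f_\mathrm{elu} = (1-\beta)\, f_\mathrm{lib} w / \langle w \rangle +
  \beta f_\mathrm{lib}$, with $\langle w \rangle$ the library-weighted
  mean weight. No binding kinetics are modeled — the underlying screen
  gives no dissociation data, so distinct elution conditions are simply
  distinct weight vectors. Background carryover is a library-proportional
  mixture with weight $\beta$ (default 0.05); it is exactly the nuisance
  replicate concordance is designed to cancel, and the screen data
  motivating the package do not quantify it, so it remains a free,
  documented parameter.
* **Weights.** `weight_model()` composes a baseline (optionally dispersed
  lognormally per peptide, emulating a continuous affinity spectrum), a
  planted set of true binders, and the per-amber-codon suppression
  penalty. `planted_variants()` builds the canonical validation set: the
  parent peptide plus single-position variants with log-spaced weights —
  matching the empirical finding that true hits of a focused screen are
  lead-sequence variants, and making consensus recovery well defined.
* **Determinism.** Every sample stream (library, each condition ×
  replicate, the lognormal weight draw) gets a sub-seed derived from the
  master seed by a fixed polynomial string hash (`derive_seed()`), so
  replicates are independent yet a bundle rerun is byte-identical.
* Base qualities are constant `I`; quality modeling belongs to upstream
  trimming glue, not to this model. The per-base substitution
  `error_rate` defaults to 0; with it, errors hit flanks and inserts
  alike, feeding the rejection tallies.

# Read processing

Inserts are located by *exact* matching of a 12-mer anchor (the suffix of
the 5' flank and the prefix of the 3' flank) on both strands, accepting
only a unique placement with exactly the scheme's insert length between
the anchors and no N inside. Exactness keeps the accept/reject contract
crisp and testable; a mismatch-tolerant mode is a deliberate non-feature
(upstream read cleaning is out of scope). Rejections are tallied by
reason (`no_flank`, `ambiguous_placement`, `wrong_length`,
`ambiguous_base`, `unsuppressed_stop`) with two conservation invariants:
scanned reads = with-insert + pre-translation rejections, and with-insert
= accepted + unsuppressed-stop. Reads with unsuppressed stops encode
clones that cannot display and are excluded from frequencies — an
explicit, tallied choice rather than a silent drop, since published
screen analyses rarely state their handling.

# Enrichment estimation

Residue-level factors are plain frequency ratios — per-position library
frequencies are large by design, so no pseudocount is applied. Peptide
-level factors use a Jeffreys-style pseudocount $a$ (default 0.5):

$$E(p) = \frac{(c_\mathrm{elu}(p)+a)/(N_\mathrm{elu}+aV)}
{(c_\mathrm{lib}(p)+a)/(N_\mathrm{lib}+aV)},$$

with $V$ the number of distinct peptides observed in either sample. A
pseudocount is unavoidable at realistic depths: a 64,000-member space
sequenced at ~184,000 library reads leaves the mean peptide with fewer
than 3 library reads and many true binders unobserved before selection.
Two estimator properties to keep in mind (both surfaced by the validation
suite):

* With $a = 0$ the estimator is ratio-unbiased but undefined for
  library-absent peptides (they are skipped with a warning). Parameter
  -recovery checks therefore use $a = 0$; ranking uses $a = 0.5$.
* With $a > 0$ and $V \gg N_\mathrm{elu}/a$ the normalization compresses
  all factors by a common scale (≈ 0.57 decades at the depths above).
  Ranking, concordance and hit calling are unaffected (the shift is
  shared), but absolute factors with pseudocounts should be read as
  scores, not unbiased ratios. The pseudocount is recorded in the
  result's metadata.

Replicate concordance joins the two factor tables over the union of
peptides detected at least once in at least one replicate *eluate* and
reports Pearson r of log10 factors — fold changes are multiplicative, and
the log scale is what makes a Pearson statistic meaningful across three
decades of enrichment. Hits must exceed the threshold (default 1.0) in
*both* replicates and are ranked by the geometric mean of the two
factors, ties broken lexicographically so ranking is a pure function of
the data. The consensus peptide takes, per randomized position, the
residue with the highest mean factor across conditions/replicates; it is
reported with the caveat that positionwise argmax ignores cooperative
residue interactions, which is precisely why per-peptide ranking, not the
consensus, selects hits.

# Validation design and problem sizes

The test suite validates each layer against an independent oracle:
brute-force 64-codon enumeration for distributions; closed-form mixture
algebra for eluate truth; exact multiset round-trips
(simulator → extraction → translation → counting) at `error_rate = 0`;
and estimator identities (self-enrichment ≡ 1, scale invariance).

Simulation-based checks run at the modeled study's scale — one library
sample of 184,511 reads, eluates of 10,898 reads, the 64,000-peptide
scheme — chosen because estimator behaviour (library undersampling,
singleton background) only shows itself there; the whole suite completes
in under a minute on one CPU. Two regimes are exercised:

* **Recovery regime**: baseline weight 1, β = 0.1, 50 planted
  lead-sequence variants with weights 10–1000. Recovered factors match
  closed-form truth within 3 multinomial σ (log scale, library and eluate
  terms combined) for every peptide with expected eluate count ≥ 50; the
  top-20 hit list is entirely planted; the consensus equals the planted
  parent. The weakest planted binders (expected eluate count ≈ 1) are
  statistically indistinguishable from background singletons — an honest
  property of single-round screening at these depths, not a defect.
* **Strong-signal regime**: only the planted binders retained (baseline
  weight 0, β = 0). The eluate-detection union is then exactly the
  planted set, every member is well covered, and replicate Pearson r on
  log10 factors exceeds 0.9 (≈ 0.99 observed). With *any* appreciable
  background at these depths the union acquires thousands of single-read
  peptides whose factors are anti-correlated between replicates
  (detected in one, zero-filled in the other), and r plateaus around
  0.75 regardless of the weight spectrum — worth remembering when
  interpreting concordance statistics on real screens. A permuted
  replicate yields |r| < 0.2.

# What the simulator does not capture

Multinomial read sampling with i.i.d. inserts omits: PCR amplification
noise and duplicates, position-correlated synthesis errors, chimeric
reads, quality degradation along the read, barcode bleed-through, and any
kinetic structure in elution series. Passing the parameter-recovery
checks therefore demonstrates correctness of the estimators under the
stated generative model, not robustness to every artefact of a real
sequencing run — upstream QC and the rejection tallies are the guard
rails there.
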