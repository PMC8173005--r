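# panenrich

Analytics for focused (secondary) phage-display peptide libraries screened
by single-round biopanning and deep sequencing.

A focused library fixes the residues of a lead peptide that are essential
for binding and randomizes the tolerant ones — hard randomization with NNK
codons, conservative two-way choices (e.g. Tyr/Phe via TWT), or soft
randomization, where a doped nucleotide mix (here 70/10/10/10 per codon
position) keeps the parent residue dominant while admitting every
substitution. After a single selection round, deep sequencing of the
pre-screened library and of the eluates turns hit identification into a
counting problem. `panenrich` covers that workflow end to end:

* **Library design math** — exact amino-acid distributions per position
  from the degenerate codon definitions, including amber-suppression
  handling (supE hosts read TAG as Gln), stop-codon burden, and the
  theoretical diversity of the stop-free peptide space.
* **Synthetic screens** — a generative simulator (naive library + replicate
  eluates as FASTQ) under a proportional-retention selection model with
  per-peptide weights `w(p, c)`, nonspecific background carryover `β`, and
  optional synthesis bias, returning closed-form truth:
  `f_elu(p) = (1−β)·f_lib(p)·w(p,c) / Σ_q f_lib(q)·w(q,c) + β·f_lib(p)`.
* **Read processing** — flank-anchored extraction of the fixed-length
  insert from reads (both strands, exact anchors), translation under the
  amber policy, and per-sample peptide/rejection tallies.
* **Enrichment analysis** — residue-level and per-peptide enrichment
  factors relative to the pre-screened library
  (`E(p) = f_elu(p) / f_lib(p)`, with a Jeffreys-style pseudocount option
  for unobserved peptides), replicate concordance (Pearson r of log10
  factors over the union of detected peptides), true-hit calling (enriched
  in **both** parallel replicates), ranking by geometric-mean factor, and
  consensus derivation.

The built-in `igg_focused_scheme()` is a nine-position library around an
IgG Fc-binding nonapeptide: Gly1 fixed, NNK at positions 2 and 7, TWT at
3, 5, 9, Trp fixed at 4 and 8, and a doped codon favouring Asp at
position 6 — a 27-bp insert encoding 64,000 distinct peptides.

## Worked example

```r
library(panenrich)

scheme <- igg_focused_scheme()
policy <- suppression_policy()        # amber -> Gln, efficiency 0.5

# what the doped codon at position 6 promises
round(100 * codon_aa_distribution(scheme$positions[[6]]$codon, policy), 1)[
  c("D", "E", "N", "M")]
#>    D    E    N    M
#> 39.2  9.8  5.6  0.1

peptide_space_size(scheme, policy)
#> [1] 64000

# simulate a two-replicate screen with one strong planted binder ...
cfg <- screen_config(scheme = scheme, conditions = "pH3.6", replicates = 2,
                     depth_library = 12000, depth_eluate = 3000,
                     background = 0.1,
                     weights = weight_model(planted = data.frame(
                       peptide = "GSYWYNVWF", weight = 5000)),
                     seed = 23)
lib  <- count_sample(sample_library(cfg)$sample, scheme, policy)
reps <- lapply(1:2, function(r)
  count_sample(sample_eluate(cfg, "pH3.6", r)$sample, scheme, policy))

# ... and recover it
pe   <- lapply(reps, peptide_enrichment, library = lib, pseudocount = 0.5)
hits <- call_hits(replicate_concordance(pe[[1]], pe[[2]]), min_factor = 1)
head(hits, 1)
#>   rank   peptide enrichment_a enrichment_b    score
#> 1    1 GSYWYNVWF     2058.764     2055.819 2057.291
```

The score is the geometric mean of the two replicate enrichment factors;
the planted binder ranks first because it is enriched in both parallel
screens, while background carryover peptides fail in at least one.

## Analysis workflow

`analysis/` contains the numbered drivers that reproduce the package's own
study, writing decision-level tables under `results/` and bulk
intermediates (FASTQ, full truth/count tables) under `scratch/`:

1. `01_library_design.R` — exact design expectations, diversity, stop burden.
2. `02_simulate_screen.R` — a study-scale screen (184,511 library reads;
   2 × 10,898 eluate reads; 50 planted lead-sequence variants; 2:1 Phe:Tyr
   synthesis skew).
3. `03_count_inserts.R` — read processing QC and expected-vs-observed
   frequency flags.
4. `04_enrichment_ranking.R` — enrichment, concordance, top-20 hits,
   consensus, and closed-form recovery validation.

Run them in order with `Rscript analysis/0X_*.R` from the repository root.

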