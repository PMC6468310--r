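---
title: "Predicting primary operons in plastid genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting primary operons in plastid genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastoperon)
```

## The problem

Plastids (chloroplasts) keep a bacterial-like genome organisation: genes are
grouped into operons — several adjacent genes transcribed as one primary RNA
from a single promoter. Unlike bacterial operons, plastid transcription
units are pervasively transcribed, heavily processed into isoforms, and
rate-limited at translation, so the sequence signatures of co-transcription
differ from the classical bacterial ones. `plastoperon` predicts, for every
pair of adjacent genes in an annotated plastome, whether the pair is
co-transcribed (an *operon pair*, OP) or independently transcribed (a
*non-operon pair*, NOP), and concatenates positive pairs into genome-wide
primary operon maps. Only an annotated genome (GenBank, or GFF3 + FASTA) is
required; no RNA-seq or other expression data.

## The model

Each genome is reduced to its circular list of adjacent gene pairs
(`enumerate_adjacent_pairs()`; n pairs for n genes, the last→first wrap pair
included once). Per pair, `compute_pair_features()` derives named numeric
features:

* **Intergenic spacer (IGS) geometry and composition** — the signed distance
  `gene3.start − gene5.end` (negative for overlapping genes) and the spacer
  GC fraction. Co-transcribed spacers are themselves transcribed, so
  selection keeps them short and AT-rich.
* **Gene-body composition** — GC of both members and its absolute margin.
* **mRNA folding-energy profiles** — a 40-nt window slid (step 1) along the
  5′ region of each gene (default −100..+50 nt around the annotated start,
  the region where plastid RNA-binding proteins act on cis-elements), each
  window scored by its minimum free energy (MFE ≤ 0 kcal/mol). Pair
  similarity is the Pearson correlation of the two aligned profiles;
  position-binned absolute energy margins are additional features.
  Co-transcribed neighbours tend to carry similar 5′ folding profiles — a
  chloroplast-specific signal tied to translation-level co-regulation.
* **Gene-pair conservation** — the fraction of reference plastomes in which
  the two gene names occur adjacently in the same relative order and
  orientation (name-based, not homology-based: plastid gene nomenclature is
  strongly standardised).
* **Codon usage and hydropathy (CDS pairs only)** — Euclidean distance
  between 59-dimensional RSCU vectors, and the absolute GRAVY
  (Kyte–Doolittle) margin of the encoded proteins.

Features that are undefined for a pair (no spacer, profile too short, mixed
schema) are *absent* (NA), never zero-filled.

### The classifier

Pairs are split into a **CDS group** (both members coding) and a **mixed
group** (tRNA/rRNA involved), because codon- and protein-level features only
exist for the former and the two groups behave differently. Per group,
`operon_rf()` fits a bootstrap ensemble: 10 rounds of a simple random 70/30
train/cross-validation split, a 1000-tree random forest per round, and the
arithmetic mean of the round accuracies (`accuracy = (TP + TN)/N`) as the
headline metric. Prediction is by majority vote of the 10 members: the score
is the fraction of votes for co-transcription, thresholded at 0.5. A score
of exactly 0.5 is called 1 — a fixed, documented tie rule rather than
platform-dependent rounding. `assemble_operons()` turns maximal runs of
positive pairs into operons; a run crossing the replication origin is one
operon, and a genome counts a gene as "in an operon" only when its unit has
at least two genes.

`backward_elimination()` wraps the ensemble in backward feature selection:
each iteration records the mean cross-validation accuracy, then drops the
feature(s) with the lowest mean impurity importance. The final set is chosen
deterministically as the smallest set within one standard deviation of the
best iteration — replacing a manual "high accuracy, few features" choice
with a reproducible rule; the full trace is returned so a human can
override.

`error_robustness()` measures tolerance to label noise: for 0..19 injected
type I (0→1) or type II (1→0) label errors it retrains the ensemble on the
corrupted labels and scores against the *original* labels.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `window`, `step` | 40 nt, 1 nt | folding-profile window and stride |
| `upstream`, `downstream` | 100 nt, 50 nt | 5′ region around the start codon |
| `rounds` | 10 | bootstrap train/cv rounds |
| `train_frac` | 0.7 | train share of each split |
| `trees` | 1000 | trees per forest |
| `threshold` | 0.5 | vote threshold (ties → 1) |
| `max_errors` | 19 | robustness-test error budget |

The 5′ region bounds are an assumption (the upstream cis-element
neighbourhood plus the ribosome-binding region); they are configurable in
`feature_config()`.

### Folding engines

Profiles accept any engine satisfying the one-function contract
"character vector of sequences → numeric MFE vector". Two are built in:

* `"builtin"` (default): a compiled weighted base-pair minimiser (G:C −3,
  A:U −2, G:U −1 kcal/mol, minimum hairpin loop 3). It is a simplified
  energy model — no stacking or loop entropies — but it is monotone in
  pairing potential, exactly 0 for unpairable homopolymers, and ~0.25 ms per
  window, which the simulator's rejection loops require.
* `"rnafold"`: ViennaRNA's `RNAfold` (full nearest-neighbour thermodynamics
  at 37 °C) via the command line. The test suite verifies that profile
  windows computed through this binding equal `RNAfold` run standalone to
  10⁻⁶ kcal/mol.

A caveat that holds for *any* engine: step-1 windows overlap by 39/40 nt, so
profile values are strongly autocorrelated. A 111-point profile has only a
handful of effective degrees of freedom, and the null distribution of the
pair correlation is accordingly wide (sd ≈ 0.6) though centred on zero.
Classification is unaffected (the feature still separates the classes in
expectation), but individual pair correlations should not be over-read.

## The statistics

* `permutation_test()` — pools the two vectors and redistributes them,
  keeping the original sizes; the P-value is the fraction of permuted
  absolute mean margins strictly exceeding the observed one (no
  pseudo-count). A zero count escalates the permutation number tenfold once;
  if still zero the P-value is censored and reported as a bound
  (`P < 10⁻⁵` at the default 10⁴→10⁵ escalation), never as 0. Two special
  rules are documented rather than silent: an observed margin of exactly 0
  returns P = 1, and redistribution always draws the smaller group's size
  from the sorted pool so the test is exactly symmetric in its arguments.
* `empiric_pvalue()` — repeatedly draws 50-element samples from each group
  and reports the fraction of rounds in which the directional relation
  between sample means holds; ≈0.5 means no difference, ≈1 supports the
  relation.
* `enrichment_index()` — `((X/N) − (K/M))/(X/N)` for a gene class with X
  operon members among N operon genes and K members among M genes; bounded
  above by 1, −∞ ("fully depleted") at X = 0.
  `hypergeometric_enrichment()` attaches the matching upper or lower
  hypergeometric tail. `bh_fdr()` applies Benjamini–Hochberg step-up
  adjustment.
* `functional_enrichment_resampling()` — scores resampled operons by the
  fraction of internal adjacent pairs sharing a functional class, against
  the same sampling on a label-shuffled map (two-tailed rank-sum z and P).
  Caveat: drawing many more samples than there are distinct multi-gene
  operons pseudo-replicates tiny multiset differences and inflates |z| even
  under a random-label null; keep `n_samples` within an order of magnitude
  of the operon count when the null matters.

## The synthetic-plastome generator

`simulate_plastome()` emits a seeded, fully deterministic circular annotated
genome with known truth labels, so every pipeline stage is testable without
downloads. It draws transcription-unit sizes (1–6 genes), assigns gene
classes (≈75% CDS, ≈19% tRNA, ≈6% rRNA, with RNA genes preferentially
monocistronic), synthesises stop-free GC-tuned coding sequences, and plants
three OP-vs-NOP contrasts:

* OP spacers shorter than NOP spacers (strong preset: 80 ± 20 vs
  280 ± 70 nt),
* OP spacers lower in GC (0.18 vs 0.45),
* correlated 5′ folding profiles in OP pairs: the downstream member's 5′
  region starts as a copy of its partner's (written only into the spacer,
  plus the first 16 codons when both members are coding, keeping frames
  stop-free) and is mutated until the profile Pearson r enters the target
  band (0.75 ± 0.05), with an AT-ward "squeeze" phase that restores the
  configured spacer GC while staying in band.

Short spacers lock most of the 150-nt window inside the upstream gene's
body, capping the reachable correlation; such pairs keep the
maximal-correlation copy, and only if most OP pairs miss the band is the
configuration rejected. `effect_scale` interpolates every contrast —
including within-unit strand coherence, via a per-gene flip probability
(1 − s)/2 — linearly toward the NOP parameters, so at 0 the two classes are
generated exchangeably (a proper null genome). The `"realistic"` preset
overlaps the class distributions the way real plastome features overlap;
the default `"strong"` preset separates them nearly noiselessly for fast,
sharp tests.

What the generator does *not* emulate: introns and RNA editing, transcript
processing, promoter motifs, genuine phylogenetic structure in the
reference panels (these are shuffled-block rearrangements of the same gene
order), and real codon-usage landscapes. Passing tests therefore
demonstrate that the implementation recovers planted structure of the kind
the features target — not that the classifier attains any particular
accuracy on real plastomes.

## Study conditions used by the checks

The test suite and `scripts/acceptance.R` size their experiments as
follows, as the package's own choices: feature-distribution and
parameter-recovery checks use a strong-preset genome of ~580 genes
(≥200 pairs per class, sampled 200 + 200 for training); the null check uses
`effect_scale = 0` at 240 genes; the label-error experiment runs at
`effect_scale = 0.55` of the realistic preset, which puts the baseline
cross-validation accuracy in the mid-80s — the regime of the published
empirical dataset — because at saturating planted effects a forest simply
outvotes mislabelled training pairs and the error curve flattens;
end-to-end operon recovery trains on a 240-gene strong genome and predicts
a held-out 150-gene genome; the transfer check pools four 110-gene genomes
and leaves each out in turn.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally; GenBank's 1-based inclusive
  convention is converted on read and write.
* Overlapping genes have negative spacer length and *no* spacer GC (the
  feature is absent, not 0).
* Missing feature values are median-imputed inside the classifier (columns
  that are entirely absent for a group are dropped); imputation medians are
  stored in the fitted object and reused at prediction.
* A random 70/30 split of a small, imbalanced group can leave one class out
  of the train part; such splits are redrawn (bounded retries) rather than
  crashing — the split remains otherwise simple random, as specified, with
  stratification deliberately not the default.
* Constant features are removed before backward elimination with a warning.
* Vote ties at exactly 0.5 are called 1; `strict_strand = TRUE` optionally
  forces opposite-strand pairs to 0 (by default they are classified like
  any other pair, with strand agreement available as a feature, since
  mixed-orientation neighbourhoods do occur around tRNAs).

## Known limitations

* The built-in folding engine ignores stacking and loop entropies; absolute
  energies are not comparable to thermodynamic MFE values (use
  `engine = "rnafold"` when absolute energies matter).
* Conservation is name-based; unnamed or non-standardly named genes yield an
  absent feature rather than a homology lookup.
* The predictor targets *primary* operons; processing of polycistrons into
  isoforms is out of scope.
* Wrap-origin operons are flagged, and their GFF3/BED records span to the
  genome end rather than being split into two blocks.
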