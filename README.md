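# plastoperon

Prediction and analysis of **primary operons in plastid (chloroplast)
genomes** from sequence alone.

Plastomes retain a bacterial-like organisation of genes into operons —
several adjacent genes transcribed as one primary RNA from a single
promoter — but plastid gene expression (pervasive transcription, heavy
transcript processing, translation-limited output) gives these units
sequence signatures of their own. `plastoperon` takes an annotated plastome
(GenBank, or GFF3 + FASTA), enumerates every pair of adjacent genes on the
circular genome, computes sequence-based features for each pair, and
classifies each pair as co-transcribed (operon pair, OP) or independently
transcribed (NOP) with a bootstrap random-forest ensemble. Positive pairs
are concatenated into genome-wide operon maps. The package is aimed at
plastid genomics and chloroplast synthetic biology, where operon context
determines how stacked transgenes can share a promoter.

## The method in brief

For each adjacent pair the features include: the signed intergenic spacer
length `gene3.start − gene5.end` and the spacer GC fraction; both gene-body
GC contents and their margin; strand agreement; the similarity of the two
genes' 5′ mRNA folding-energy profiles (40-nt sliding windows over
−100..+50 nt around each start codon, scored by minimum free energy;
similarity is the Pearson correlation of the aligned profiles, a
chloroplast-specific operon signal) plus position-binned energy margins;
name-based gene-pair conservation across a reference panel; and, for
CDS-only pairs, the Euclidean distance between 59-dimensional RSCU
(relative synonymous codon usage) vectors and the absolute GRAVY
(Kyte–Doolittle hydropathy) margin.

Pairs are modelled in two groups — both-CDS versus mixed (tRNA/rRNA
involved) — each with its own ensemble: 10 bootstrap rounds of a random
70/30 train/cross-validation split, 1000 trees per round, headline metric
`accuracy = (TP + TN)/N` averaged over rounds, and majority voting (score =
fraction of votes, threshold 0.5) at prediction time. Supporting machinery
implements wrapped backward feature elimination, a label-error robustness
test (up to 19 injected type I/II errors), a permutation test with censored
P-values (`P < 10⁻⁵`), an empiric P-value, a gene-class enrichment index
`((X/N) − (K/M))/(X/N)` with hypergeometric tails and BH-FDR, and a
functional-enrichment resampling comparison. A seeded synthetic-plastome
generator with planted operon structure makes the whole pipeline testable
hermetically; see the vignette (`vignettes/operon-prediction.Rmd`) for the
model, parameter and design details.

## Worked example

```r
library(plastoperon)

sim    <- simulate_plastome(sim_config(n_genes = 80, seed = 2024))
pairs  <- enumerate_adjacent_pairs(sim$plastome)
feats  <- compute_pair_features(pairs, sim$plastome)
labels <- sim$truth$label[match(feats$pair_id, sim$truth$pair_id)]

cls  <- train_operon_classifier(feats, labels, trees = 1000, seed = 7)
pred <- predict(cls, feats)
map  <- assemble_operons(pred, sim$plastome)

print(sim)
#> <sim_plastome> seed 2024 (strong preset, effect 1.00): 80 genes, 31 units, 49 OP / 31 NOP pairs
print(cls)
#> <operon_classifier>
#>   CDS group: mean cv accuracy 0.987 (47 pairs)
#>   mixed group: mean cv accuracy 0.950 (33 pairs)
summary(map)
#> Operon map of synpl002024: 31 units (20 polycistronic)
#>   CDSs in operons:  100.0%
#>   all genes in operons: 86.2%
```

The simulated genome plants 31 transcription units; the per-group mean
cross-validation accuracies (0.987 / 0.950) are the fraction of held-out
pairs classified correctly per bootstrap round, and the map summary reports
how many genes end up inside multi-gene operons. Gene-class composition of
the map feeds the enrichment statistics — here tRNAs lean monocistronic
(index −0.44, hypergeometric P = 0.004) while rRNAs are fully depleted:

```r
operon_class_enrichment(map)
#>   class  X  N  K  M enrichment_index      p_value
#> 1   CDS 60 69 60 80           0.1375 1.603027e-08
#> 2  rRNA  0 69  5 80             -Inf 1.921796e-05
#> 3  tRNA  9 69 15 80          -0.4375 4.389253e-03

permutation_test(feats$igs_length[labels == 1], feats$igs_length[labels == 0])
#> Permutation test on the absolute margin between group means
#>   observed margin: 194.9;  permutations: 100000
#>   P < 1e-05 (censored)
```

A command-line interface wrapping the same functions is installed at
`exec/plastoperon` (subcommands `simulate`, `features`, `train`, `predict`,
`assemble`, `stats`; run `plastoperon --help`).

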