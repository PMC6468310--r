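Package: plastoperon
Title: Primary Operon Prediction and Analysis for Plastid Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts primary operons (co-transcribed adjacent gene pairs) in
    annotated plastid genomes. Parses GenBank or GFF3+FASTA plastome
    annotations, enumerates adjacent gene pairs on the circular genome,
    computes sequence-based pair features including sliding-window RNA
    folding-energy profiles, intergenic spacer length and GC content, gene
    pair conservation, codon-usage and hydropathy margins, and classifies
    each pair with a bootstrap random-forest ensemble trained separately for
    coding-sequence and mixed gene pairs. Classified pairs are concatenated
    into genome-wide operon maps. Includes the accompanying resampling
    statistics (permutation test with censored P-values, empiric P-value,
    gene-class enrichment index with hypergeometric tests, functional
    enrichment resampling), a label-error robustness test, wrapped backward
    feature elimination, and a seeded synthetic-plastome generator with
    planted operon structure for hermetic end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    methods,
    randomForest,
    Rcpp,
    rtracklayer,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
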