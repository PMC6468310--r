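## Shared fixtures. Simulated genomes are cached per session because the
## generator's profile planting is the expensive step.

.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(key, config) {
  if (is.null(.sim_cache[[key]]))
    assign(key, simulate_plastome(config), envir = .sim_cache)
  .sim_cache[[key]]
}

cached_features <- function(key, sim, ...) {
  fkey <- paste0(key, "_features")
  if (is.null(.sim_cache[[fkey]])) {
    pairs <- enumerate_adjacent_pairs(sim$plastome)
    assign(fkey, compute_pair_features(pairs, sim$plastome, ...),
           envir = .sim_cache)
  }
  .sim_cache[[fkey]]
}

truth_labels <- function(sim, features) {
  sim$truth$label[match(features$pair_id, sim$truth$pair_id)]
}

## a small hand-written GenBank record: plus/minus strands, a join, a
## pseudogene to skip, tRNA and rRNA feature keys
write_tiny_genbank <- function(path) {
  seq60 <- paste(rep("acgtacgtag", 60), collapse = "")   # 600 nt
  writeLines(c(
    "LOCUS       toyplast                 600 bp    DNA     circular PLN 01-JAN-2026",
    "DEFINITION  hand-written toy plastome.",
    "ACCESSION   toyplast",
    "FEATURES             Location/Qualifiers",
    "     source          1..600",
    "     CDS             11..100",
    '                     /gene="psbA"',
    '                     /product="photosystem II protein D1"',
    "     CDS             complement(121..210)",
    '                     /gene="rbcL"',
    "     CDS             join(231..290,301..330)",
    '                     /gene="petB"',
    "     tRNA            351..420",
    '                     /gene="trnE"',
    "     rRNA            441..560",
    '                     /gene="rrn16"',
    "     CDS             571..590",
    '                     /gene="brokenX"',
    "                     /pseudo",
    "ORIGIN",
    vapply(seq(1, 600, 60), function(st) {
      chunk <- substr(seq60, st, st + 59)
      blocks <- substring(chunk, seq(1, 60, 10), seq(10, 60, 10))
      sprintf("%9d %s", st, paste(blocks, collapse = " "))
    }, character(1)),
    "//"), path)
  invisible(path)
}

## labelled feature set with planted informative features and pure noise
planted_feature_set <- function(n = 200L, n_inform = 5L, n_noise = 20L,
                                shift = 1.5, seed = 1L) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  x <- as.data.frame(c(
    lapply(seq_len(n_inform), function(i) rnorm(n, mean = shift * y)),
    lapply(seq_len(n_noise), function(i) rnorm(n))))
  names(x) <- c(sprintf("inform_%02d", seq_len(n_inform)),
                sprintf("noise_%02d", seq_len(n_noise)))
  list(x = x, y = y,
       informative = sprintf("inform_%02d", seq_len(n_inform)))
}

## manual plastome builder for pair/assembly edge cases
toy_plastome <- function(starts, ends, strands = NULL, types = NULL,
                         L = max(ends) + 50L, circular = TRUE,
                         ids = NULL) {
  n <- length(starts)
  set.seed(99L)
  plastome("toy",
           paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                 collapse = ""),
           data.frame(gene_id = ids %||% sprintf("g%02d", seq_len(n)),
                      gene_type = types %||% rep("CDS", n),
                      strand = strands %||% rep("+", n),
                      start = as.integer(starts), end = as.integer(ends),
                      stringsAsFactors = FALSE),
           circular = circular)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
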