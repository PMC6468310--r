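## Per-pair sequence features: nucleotide composition, 5'UTR folding-profile
## similarity, codon-usage and hydropathy margins, and name-based gene-pair
## conservation across a reference panel.

#' GC content of a nucleotide sequence
#'
#' `(#G + #C) / (#A + #C + #G + #T)`; N (and other ambiguity codes, which are
#' normalised to N) are excluded from numerator and denominator. Undefined
#' (NA) for empty or all-N input, so that the feature is omitted rather than
#' reported as 0.
#'
#' @param seq nucleotide string (or character vector).
#' @return numeric fraction(s) in `[0, 1]`, `NA_real_` when undefined.
#' @export
gc_content <- function(seq) {
  vapply(seq, function(s) {
    s <- normalize_seq(s)
    gc <- nchar(gsub("[^GC]", "", s))
    acgt <- nchar(gsub("[^ACGT]", "", s))
    if (acgt == 0L) NA_real_ else gc / acgt
  }, numeric(1), USE.NAMES = FALSE)
}

#' Extract the 5' region around a gene's translational start
#'
#' Returns the strand-corrected sequence running from `upstream` nt before
#' the annotated start through `downstream` nt into the gene (so the start
#' codon sits at position `upstream + 1` of the result). On circular genomes
#' the region wraps the origin; on linear genomes it is truncated at the ends
#' with a warning.
#'
#' @param x a `plastome`.
#' @param gene `gene_id` or row index.
#' @param upstream,downstream extent in nt (defaults 100 and 50). The default
#'   window brackets the upstream cis-element region where plastid RNA-binding
#'   proteins act, plus the ribosome-binding neighbourhood of the start.
#' @return nucleotide string in transcript orientation.
#' @export
extract_utr5 <- function(x, gene, upstream = 100L, downstream = 50L) {
  i <- if (is.character(gene)) match(gene, x$genes$gene_id) else gene
  if (is.na(i)) stop2("unknown gene: ", gene)
  g <- x$genes[i, ]
  L <- genome_length(x)
  if (g$strand == "+") { s0 <- g$start - upstream; e0 <- g$start + downstream }
  else { s0 <- g$end - downstream; e0 <- g$end + upstream }
  if (!x$circular && (s0 < 0L || e0 > L))
    warning(sprintf("5' region of %s truncated at the linear genome edge",
                    g$gene_id))
  s <- seq_window(x, s0, e0)
  if (g$strand == "-") revcomp(s) else s
}

## -- codon usage ------------------------------------------------------------

synonymous_families <- function() {
  code <- Biostrings::GENETIC_CODE
  code <- code[code != "*"]
  fam <- split(names(code), code)
  fam[vapply(fam, length, integer(1)) > 1L]   # drop Met, Trp: no synonymy
}

#' Relative synonymous codon usage (RSCU)
#'
#' Observed codon count divided by its expectation under uniform synonymous
#' use, over the 59 codons belonging to multi-codon amino-acid families (stop
#' codons and the single-codon Met/Trp families are excluded). Codons of
#' amino acids absent from the protein get RSCU 0.
#'
#' @param cds canonical coding sequence (length divisible by 3).
#' @return named numeric vector of 59 RSCU values.
#' @export
rscu <- function(cds) {
  s <- normalize_seq(cds)
  if (nchar(s) %% 3L != 0L) stop2("CDS length not divisible by 3")
  codons <- substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
  fam <- synonymous_families()
  out <- numeric(0)
  for (aa in names(fam)) {
    members <- fam[[aa]]
    counts <- vapply(members, function(cd) sum(codons == cd), numeric(1))
    tot <- sum(counts)
    vals <- if (tot == 0) rep(0, length(members))
            else counts / (tot / length(members))
    out <- c(out, setNames(vals, members))
  }
  out
}

#' Codon-usage-bias distance between two coding sequences
#'
#' Euclidean distance between the genes' RSCU vectors; 0 iff the two genes
#' use synonymous codons identically.
#'
#' @param cds5,cds3 canonical coding sequences.
#' @return non-negative real.
#' @export
codon_usage_distance <- function(cds5, cds3) {
  sqrt(sum((rscu(cds5) - rscu(cds3))^2))
}

## -- hydropathy -------------------------------------------------------------

## Kyte-Doolittle hydropathy scale
kd_scale <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
              E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
              M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
              Y = -1.3, V = 4.2)

translate_cds <- function(cds) {
  s <- normalize_seq(cds)
  if (nchar(s) %% 3L != 0L) stop2("CDS length not divisible by 3")
  codons <- substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"                       # ambiguous codons
  body <- paste(aa, collapse = "")
  body <- sub("\\*$", "", body)
  star <- regexpr("*", body, fixed = TRUE)
  if (star > 0)
    stop2("internal stop codon at residue ", star)
  body
}

#' Grand average of hydropathy (GRAVY) of the encoded protein
#'
#' Mean Kyte-Doolittle hydropathy over residues, terminal stop excluded.
#'
#' @param cds canonical coding sequence.
#' @return numeric GRAVY value.
#' @export
gravy <- function(cds) {
  aa <- strsplit(translate_cds(cds), "")[[1L]]
  vals <- kd_scale[aa]
  mean(vals, na.rm = TRUE)
}

#' Hydropathy margin between two coding sequences
#'
#' `|GRAVY(cds5) - GRAVY(cds3)|`; invariant to synonymous recoding since it
#' is defined at the protein level.
#'
#' @param cds5,cds3 canonical coding sequences.
#' @return non-negative real.
#' @export
gravy_margin <- function(cds5, cds3) abs(gravy(cds5) - gravy(cds3))

## -- conservation -----------------------------------------------------------

normalize_gene_name <- function(x) tolower(sub("_[0-9]+$", "", x))

adjacency_bigrams <- function(ref) {
  g <- ref$genes
  n <- nrow(g)
  if (n < 2L) return(data.frame(a = character(), b = character(),
                                sa = character(), sb = character()))
  i5 <- if (ref$circular) seq_len(n) else seq_len(n - 1L)
  i3 <- if (ref$circular) c(seq_len(n)[-1L], 1L) else i5 + 1L
  data.frame(a = normalize_gene_name(g$gene_id[i5]),
             b = normalize_gene_name(g$gene_id[i3]),
             sa = g$strand[i5], sb = g$strand[i3], stringsAsFactors = FALSE)
}

flip_strand <- function(s) ifelse(s == "+", "-", "+")

#' Gene-pair conservation across a reference panel
#'
#' Fraction of reference genomes in which genes matching the pair members'
#' names (case-insensitive, coordinate disambiguation suffix stripped) occur
#' adjacently in the same relative order and orientation. The arrangement
#' read from the opposite strand (reversed order, both strands flipped)
#' counts as the same orientation. NA when either gene is unnamed.
#'
#' @param pair one row of a `gene_pairs` data.frame.
#' @param x the `plastome` the pair came from (for member strands).
#' @param references list of `plastome` objects.
#' @return fraction in `[0, 1]`, or `NA_real_`.
#' @export
pair_conservation <- function(pair, x, references) {
  if (length(references) == 0L) stop2("reference panel is empty")
  g <- x$genes
  s5 <- g$strand[match(pair$gene5, g$gene_id)]
  s3 <- g$strand[match(pair$gene3, g$gene_id)]
  n5 <- normalize_gene_name(pair$gene5)
  n3 <- normalize_gene_name(pair$gene3)
  if (!nzchar(n5) || !nzchar(n3) || is.na(s5) || is.na(s3)) return(NA_real_)
  hits <- vapply(references, function(ref) {
    bg <- adjacency_bigrams(ref)
    fwd <- bg$a == n5 & bg$b == n3 &
      ((bg$sa == s5) == (bg$sb == s3))          # same relative orientation
    rev <- bg$a == n3 & bg$b == n5 &
      ((bg$sa == flip_strand(s3)) == (bg$sb == flip_strand(s5)))
    any(fwd) || any(rev)
  }, logical(1))
  mean(hits)
}

## -- assembled feature matrix -----------------------------------------------

#' Feature computation settings
#'
#' @param window,step folding-profile window width and step (nt).
#' @param upstream,downstream 5' region extent around the start (nt).
#' @param engine folding engine, see [mfe()].
#' @param margin_bins number of positional bins for the per-pair
#'   folding-margin features.
#' @return a list of settings for [compute_pair_features()].
#' @export
feature_config <- function(window = 40L, step = 1L, upstream = 100L,
                           downstream = 50L, engine = "builtin",
                           margin_bins = 10L) {
  list(window = as.integer(window), step = as.integer(step),
       upstream = as.integer(upstream), downstream = as.integer(downstream),
       engine = engine, margin_bins = as.integer(margin_bins))
}

#' Compute the per-pair feature matrix
#'
#' Assembles, for every adjacent gene pair, the named numeric features used
#' by the classifier: signed intergenic length, spacer GC, the two gene-body
#' GC contents and their absolute margin, strand agreement, 5'-region
#' folding-profile Pearson similarity and mean absolute energy margin plus
#' `margin_bins` position-binned folding margins, and - for pure-CDS pairs
#' with canonical reading frames - the RSCU distance and GRAVY margin.
#' Features that are undefined for a pair (no spacer, too-short profile,
#' mixed schema) are NA, never zero-filled. `pair_conservation` is included
#' only when a reference panel is supplied.
#'
#' @param pairs `gene_pairs` data.frame from [enumerate_adjacent_pairs()].
#' @param x the `plastome` the pairs came from.
#' @param references optional list of `plastome` objects for the
#'   conservation feature.
#' @param config a [feature_config()].
#' @return data.frame with identifier columns `pair_id`, `gene5`, `gene3`,
#'   `pair_group` followed by numeric feature columns.
#' @export
compute_pair_features <- function(pairs, x, references = NULL,
                                  config = feature_config()) {
  if (nrow(pairs) == 0L) stop2("no pairs to featurise")
  g <- x$genes
  ids <- unique(c(pairs$gene5, pairs$gene3))

  utr <- lapply(ids, function(id)
    extract_utr5(x, id, config$upstream, config$downstream))
  names(utr) <- ids
  prof <- lapply(utr, function(s)
    suppressWarnings(folding_profile(s, config$window, config$step,
                                     config$engine)))
  gseq <- lapply(ids, function(id) gene_sequence(x, id))
  names(gseq) <- ids
  body_gc <- vapply(gseq, gc_content, numeric(1))

  nb <- config$margin_bins
  rows <- lapply(seq_len(nrow(pairs)), function(k) {
    p <- pairs[k, ]
    i5 <- match(p$gene5, g$gene_id); i3 <- match(p$gene3, g$gene_id)
    f <- list(
      igs_length = as.numeric(p$igs_length),
      igs_gc = if (p$igs_length > 0L) gc_content(igs_sequence(x, p)) else NA_real_,
      cds_gc_5 = unname(body_gc[p$gene5]),
      cds_gc_3 = unname(body_gc[p$gene3]),
      same_strand = as.numeric(p$same_strand))
    f$gc_margin <- abs(f$cds_gc_5 - f$cds_gc_3)
    p5 <- prof[[p$gene5]]; p3 <- prof[[p$gene3]]
    f$fold_profile_pearson <- profile_similarity(p5, p3)
    m <- min(length(p5$energies), length(p3$energies))
    if (m >= 1L) {
      d <- abs(p5$energies[seq_len(m)] - p3$energies[seq_len(m)])
      f$fold_profile_mean_abs_margin <- mean(d)
      bin <- ceiling(seq_len(m) * nb / m)
      bm <- vapply(seq_len(nb), function(b)
        if (any(bin == b)) mean(d[bin == b]) else NA_real_, numeric(1))
    } else {
      f$fold_profile_mean_abs_margin <- NA_real_
      bm <- rep(NA_real_, nb)
    }
    names(bm) <- sprintf("fold_margin_b%02d", seq_len(nb))
    f <- c(f, as.list(bm))
    if (!is.null(references))
      f$pair_conservation <- pair_conservation(p, x, references)
    if (p$pair_group == "CDS" && !g$non_canonical[i5] && !g$non_canonical[i3]) {
      f$cub_distance <- codon_usage_distance(gseq[[p$gene5]], gseq[[p$gene3]])
      f$gravy_margin <- tryCatch(gravy_margin(gseq[[p$gene5]], gseq[[p$gene3]]),
                                 error = function(e) NA_real_)
    } else {
      f$cub_distance <- NA_real_
      f$gravy_margin <- NA_real_
    }
    unlist(f)
  })
  feats <- as.data.frame(do.call(rbind, rows))

  ## a pair with most of its applicable schema missing signals broken input
  applicable <- ifelse(pairs$pair_group == "CDS", ncol(feats), ncol(feats) - 2L)
  n_missing <- rowSums(is.na(feats)) - ifelse(pairs$pair_group == "CDS", 0L, 2L)
  if (any(n_missing > applicable / 2))
    stop2("more than half of the applicable features are undefined for pair(s) ",
          paste(head(pairs$pair_id[n_missing > applicable / 2], 5L),
                collapse = ", "))

  cbind(pairs[, c("pair_id", "gene5", "gene3", "pair_group")], feats,
        stringsAsFactors = FALSE)
}

#' Identify the numeric feature columns of a feature matrix
#' @param features a data.frame from [compute_pair_features()].
#' @return character vector of feature column names.
#' @export
feature_columns <- function(features) {
  setdiff(names(features), c("pair_id", "gene5", "gene3", "pair_group", "label"))
}

#' Write a feature matrix as TSV
#'
#' Missing features are written as empty cells, never as 0.
#'
#' @param features data.frame from [compute_pair_features()].
#' @param path output file.
#' @param labels optional 0/1 vector aligned with rows, written as a `label`
#'   column.
#' @return `path`, invisibly.
#' @export
write_feature_tsv <- function(features, path, labels = NULL) {
  out <- features
  if (!is.null(labels)) out <- cbind(out[, 1:4], label = labels,
                                     out[, -(1:4), drop = FALSE])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}
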