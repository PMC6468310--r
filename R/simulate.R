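## Seeded synthetic circular plastomes with planted operon structure and
## known truth labels, so every pipeline stage can be exercised hermetically.
## Co-transcribed (OP) pairs get shorter, lower-GC intergenic spacers and
## correlated 5'-region folding-energy profiles relative to independent
## (NOP) pairs; tRNA/rRNA genes are biased toward the monocistronic form.

#' Simulation settings
#'
#' The `"strong"` preset plants well-separated OP/NOP feature distributions
#' (fast, near-noiseless recovery for tests); `"realistic"` overlaps them the
#' way real plastome feature distributions overlap. `effect_scale`
#' interpolates every OP parameter linearly toward its NOP counterpart:
#' at 0 the two classes are generated identically (a null genome).
#'
#' @param preset `"strong"` or `"realistic"`.
#' @param n_genes number of genes (plastomes carry roughly 100-250).
#' @param class_mix fractions of CDS/tRNA/rRNA genes.
#' @param operon_length_probs probabilities of transcription-unit sizes
#'   1..k.
#' @param op_igs_length,nop_igs_length `c(mean, sd)` of spacer length (nt)
#'   for OP and NOP pairs.
#' @param op_igs_gc,nop_igs_gc spacer GC fraction per class.
#' @param fold_profile_correlation_op target folding-profile Pearson r
#'   planted between the 5' regions of OP pair members (band of +/- 0.05).
#' @param effect_scale in `[0, 1]`; scales all OP-vs-NOP contrasts.
#' @param genome_gc GC fraction of gene bodies.
#' @param cds_length_range,trna_length,rrna_length gene lengths (nt).
#' @param seed integer seed; the whole simulation is deterministic given the
#'   config.
#' @return a `sim_config` list.
#' @export
sim_config <- function(preset = c("strong", "realistic"),
                       n_genes = 120L,
                       class_mix = c(CDS = 0.75, tRNA = 0.19, rRNA = 0.06),
                       operon_length_probs =
                         c(`1` = 0.35, `2` = 0.20, `3` = 0.18,
                           `4` = 0.12, `5` = 0.09, `6` = 0.06),
                       op_igs_length = NULL, nop_igs_length = NULL,
                       op_igs_gc = NULL, nop_igs_gc = NULL,
                       fold_profile_correlation_op = NULL,
                       effect_scale = 1,
                       genome_gc = 0.35,
                       cds_length_range = c(300L, 900L),
                       trna_length = 75L, rrna_length = 600L,
                       seed = 1L) {
  preset <- match.arg(preset)
  def <- if (preset == "strong") {
    list(op_igs_length = c(mean = 80, sd = 20),
         nop_igs_length = c(mean = 280, sd = 70),
         op_igs_gc = 0.18, nop_igs_gc = 0.45,
         fold_profile_correlation_op = 0.75)
  } else {
    list(op_igs_length = c(mean = 70, sd = 30),
         nop_igs_length = c(mean = 180, sd = 100),
         op_igs_gc = 0.28, nop_igs_gc = 0.38,
         fold_profile_correlation_op = 0.55)
  }
  stopifnot(effect_scale >= 0, effect_scale <= 1,
            abs(sum(class_mix) - 1) < 1e-6)
  cfg <- list(
    preset = preset, n_genes = as.integer(n_genes), class_mix = class_mix,
    operon_length_probs = operon_length_probs / sum(operon_length_probs),
    op_igs_length = op_igs_length %||% def$op_igs_length,
    nop_igs_length = nop_igs_length %||% def$nop_igs_length,
    op_igs_gc = op_igs_gc %||% def$op_igs_gc,
    nop_igs_gc = nop_igs_gc %||% def$nop_igs_gc,
    fold_profile_correlation_op =
      fold_profile_correlation_op %||% def$fold_profile_correlation_op,
    effect_scale = effect_scale, genome_gc = genome_gc,
    cds_length_range = as.integer(cds_length_range),
    trna_length = as.integer(trna_length),
    rrna_length = as.integer(rrna_length),
    seed = as.integer(seed))
  if (effect_scale > 0 &&
      cfg$op_igs_length["mean"] >= cfg$nop_igs_length["mean"])
    stop2("OP spacers must be shorter than NOP spacers when effect_scale > 0")
  class(cfg) <- "sim_config"
  cfg
}

rand_bases <- function(n, gc) {
  if (n <= 0L) return(character(0))
  sample(c("A", "T", "G", "C"), n, replace = TRUE,
         prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
}

## random stop-free coding sequence: ATG + GC-tuned codons + TAA
rand_cds <- function(len, gc) {
  stopifnot(len %% 3L == 0L, len >= 9L)
  n_codons <- len %/% 3L - 2L
  codons <- apply(expand.grid(b1 = c("A","C","G","T"), b2 = c("A","C","G","T"),
                              b3 = c("A","C","G","T")), 1L, paste0,
                  collapse = "")
  codons <- codons[!codons %in% c("TAA", "TAG", "TGA")]
  w <- vapply(strsplit(codons, ""), function(b)
    prod(ifelse(b %in% c("G", "C"), gc / 2, (1 - gc) / 2)), numeric(1))
  paste0("ATG", paste(sample(codons, n_codons, replace = TRUE, prob = w),
                      collapse = ""), "TAA")
}

complement_chars <- function(v) chartr("ACGT", "TGCA", v)

#' Simulate a circular plastome with planted operon structure
#'
#' Draws transcription-unit sizes, assigns gene classes (tRNA/rRNA
#' preferentially monocistronic), synthesises stop-free coding sequences and
#' spacers with the configured OP/NOP length and GC contrasts, and plants
#' folding-profile similarity into co-transcribed pairs: the 5' region of
#' the transcriptionally downstream gene starts as a copy of its partner's
#' 5' region (written only into the spacer, and the first 16 codons when
#' both members are coding) and is then mutated until the profile Pearson r
#' falls inside the configured band. Pairs whose spacer is too locked to
#' reach the band keep the maximal-correlation copy; if more than half of
#' the OP pairs miss the band the configuration is rejected with an error
#' suggesting a lower target.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_plastome`: `plastome` (a [plastome()]),
#'   `truth` (data.frame `pair_id`, `gene5`, `gene3`, `label`), `operons`
#'   (planted gene_id lists), `achieved_r` (per-OP-pair planted correlation),
#'   `config`.
#' @export
simulate_plastome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  s <- config$effect_scale
  blend <- function(op, nop) nop + s * (op - nop)
  op_len_mean <- blend(config$op_igs_length[["mean"]],
                       config$nop_igs_length[["mean"]])
  op_len_sd <- blend(config$op_igs_length[["sd"]],
                     config$nop_igs_length[["sd"]])
  op_gc <- blend(config$op_igs_gc, config$nop_igs_gc)
  target_r <- s * config$fold_profile_correlation_op

  ## -- transcription-unit sizes and gene classes ----------------------------
  n <- config$n_genes
  lens <- as.integer(names(config$operon_length_probs))
  sizes <- integer(0)
  while (sum(sizes) < n)
    sizes <- c(sizes, sample(lens, 1L, prob = config$operon_length_probs))
  excess <- sum(sizes) - n
  if (excess > 0L) {
    sizes[length(sizes)] <- sizes[length(sizes)] - excess
    if (sizes[length(sizes)] == 0L) sizes <- sizes[-length(sizes)]
  }
  n_op_units <- length(sizes)
  operon_of <- rep.int(seq_len(n_op_units), sizes)

  n_trna <- round(config$class_mix[["tRNA"]] * n)
  n_rrna <- round(config$class_mix[["rRNA"]] * n)
  types <- rep("CDS", n)
  resample <- function(v, k) v[sample.int(length(v), k)]
  singles <- which(sizes == 1L)
  single_slots <- which(operon_of %in% singles)
  rna_slots <- if (length(single_slots) >= n_trna + n_rrna)
    resample(single_slots, n_trna + n_rrna)
  else c(single_slots, resample(setdiff(seq_len(n), single_slots),
                                n_trna + n_rrna - length(single_slots)))
  if (n_rrna > 0L) types[rna_slots[seq_len(n_rrna)]] <- "rRNA"
  if (n_trna > 0L) types[rna_slots[n_rrna + seq_len(n_trna)]] <- "tRNA"

  ## strand coherence within a transcription unit is itself an OP-vs-NOP
  ## contrast, so it scales with effect_scale too: at 0 strands are
  ## independent across genes and the two classes are exchangeable
  unit_strand <- sample(c("+", "-"), n_op_units, replace = TRUE)
  strands <- unit_strand[operon_of]
  flip <- runif(n) < (1 - s) / 2
  strands[flip] <- ifelse(strands[flip] == "+", "-", "+")

  ## -- per-gene transcript sequences ---------------------------------------
  counters <- c(CDS = 0L, tRNA = 0L, rRNA = 0L)
  prefix <- c(CDS = "cds", tRNA = "trn", rRNA = "rrn")
  gene_ids <- character(n)
  tx_seq <- character(n)
  for (i in seq_len(n)) {
    counters[types[i]] <- counters[types[i]] + 1L
    gene_ids[i] <- sprintf("%s%03d", prefix[[types[i]]], counters[types[i]])
    tx_seq[i] <- switch(
      types[i],
      CDS = rand_cds(3L * sample(seq(config$cds_length_range[1L] %/% 3L,
                                     config$cds_length_range[2L] %/% 3L), 1L),
                     config$genome_gc),
      tRNA = paste(rand_bases(config$trna_length, config$genome_gc),
                   collapse = ""),
      rRNA = paste(rand_bases(config$rrna_length, config$genome_gc),
                   collapse = ""))
  }
  gene_len <- nchar(tx_seq)

  ## -- pair labels and spacers ---------------------------------------------
  labels <- as.integer(operon_of == c(operon_of[-1L], operon_of[1L]))
  igs_gc_by <- ifelse(labels == 1L, op_gc, config$nop_igs_gc)
  igs_len <- integer(n)
  for (i in seq_len(n)) {
    p <- if (labels[i] == 1L) c(op_len_mean, op_len_sd)
         else c(config$nop_igs_length[["mean"]], config$nop_igs_length[["sd"]])
    igs_len[i] <- max(5L, round(rnorm(1L, p[1L], p[2L])))
  }

  ## -- genome layout (gene 1 starts at the origin) --------------------------
  gene_start <- integer(n); gene_end <- integer(n)
  pos <- 0L
  chunks <- vector("list", 2L * n)
  for (i in seq_len(n)) {
    gene_start[i] <- pos
    gene_end[i] <- pos + gene_len[i]
    genomic <- if (strands[i] == "-") revcomp(tx_seq[i]) else tx_seq[i]
    chunks[[2L * i - 1L]] <- genomic
    chunks[[2L * i]] <- paste(rand_bases(igs_len[i], igs_gc_by[i]),
                              collapse = "")
    pos <- pos + gene_len[i] + igs_len[i]
  }
  L <- pos
  genome <- strsplit(paste(unlist(chunks), collapse = ""), "")[[1L]]

  ## -- plant folding-profile similarity into OP pairs -----------------------
  achieved <- numeric(0)
  if (target_r >= 0.1) {
    res <- plant_profile_similarity(
      genome, L, gene_start, gene_end, strands, types, labels,
      operon_of, n_op_units, target_r, op_gc)
    genome <- res$genome
    achieved <- res$achieved
    if (length(achieved) &&
        mean(achieved < target_r - 0.05) > 0.5)
      stop2("planted folding-profile correlation target ", target_r,
            " unreachable for most pairs; lower fold_profile_correlation_op")
  }

  genes <- data.frame(gene_id = gene_ids, gene_type = types,
                      strand = strands, start = gene_start, end = gene_end,
                      product = sprintf("synthetic %s", types),
                      stringsAsFactors = FALSE)
  pl <- plastome(sprintf("synpl%06d", config$seed),
                 paste(genome, collapse = ""), genes, circular = TRUE)
  gene3_idx <- c(seq_len(n)[-1L], 1L)
  truth <- data.frame(
    pair_id = paste(gene_ids, gene_ids[gene3_idx], sep = "|"),
    gene5 = gene_ids, gene3 = gene_ids[gene3_idx],
    label = labels, stringsAsFactors = FALSE)
  operons <- split(gene_ids, operon_of)
  names(operons) <- NULL
  structure(list(plastome = pl, truth = truth, operons = operons,
                 achieved_r = achieved, config = config),
            class = "sim_plastome")
}

#' @export
print.sim_plastome <- function(x, ...) {
  cat(sprintf("<sim_plastome> seed %d (%s preset, effect %.2f): %d genes, %d units, %d OP / %d NOP pairs\n",
              x$config$seed, x$config$preset, x$config$effect_scale,
              nrow(x$plastome$genes), length(x$operons),
              sum(x$truth$label == 1L), sum(x$truth$label == 0L)))
  invisible(x)
}

## Plant 5'-region folding-profile similarity. Pairs are processed in
## transcription order within each unit so that every source region is final
## when read. The copy is written only into the pair's own spacer (plus the
## first 16 codons when both members are CDS, keeping frames stop-free);
## spacer positions are then mutated down until the Pearson r between the
## two members' 5'-region profiles enters the target band.
plant_profile_similarity <- function(genome, L, gene_start, gene_end,
                                     strands, types, labels, operon_of,
                                     n_units, target_r, op_gc,
                                     upstream = 100L, downstream = 50L,
                                     window = 40L, max_iter = 400L) {
  n <- length(gene_start)
  gidx <- function(p) (p %% L) + 1L             # 0-based position -> index
  region_positions <- function(i) {             # transcript order, 0-based
    if (strands[i] == "+")
      seq.int(gene_start[i] - upstream, gene_start[i] + downstream - 1L)
    else
      seq.int(gene_end[i] + upstream - 1L, gene_end[i] - downstream, by = -1L)
  }
  read_region <- function(i) {
    v <- genome[gidx(region_positions(i))]
    if (strands[i] == "-") complement_chars(v) else v
  }
  fold_e <- function(v) .fold_windows_nussinov(paste(v, collapse = ""),
                                               window, 1L)
  ## refold only the windows overlapping changed positions
  refold <- function(v, e_old, changed) {
    m <- length(e_old)
    lo <- max(1L, min(changed) - window + 1L)
    hi <- min(m, max(changed))
    s <- paste(v[lo:min(length(v), hi + window - 1L)], collapse = "")
    e_old[lo:hi] <- .fold_windows_nussinov(s, window, 1L)
    e_old
  }
  ## mutation batch clustered around an anchor so the refold span stays small
  pick_near <- function(pool, k) {
    a <- pool[sample.int(length(pool), 1L)]
    near <- pool[abs(pool - a) <= 12L]
    near[sample.int(length(near), min(k, length(near)))]
  }
  cor0 <- function(e1, e2) {
    if (sd(e1) == 0 || sd(e2) == 0) return(0)
    cor(e1, e2)
  }
  achieved <- numeric(0)

  for (u in seq_len(n_units)) {
    members <- which(operon_of == u)
    if (length(members) < 2L) next
    pair_order <- if (strands[members[1L]] == "+") members[-length(members)]
                  else rev(members[-length(members)])
    for (i5 in pair_order) {
      i3 <- if (i5 == n) 1L else i5 + 1L
      if (strands[i5] != strands[i3]) next   # no shared 5' geometry to plant
      ## transcription-upstream member is the source; its partner's 5'
      ## region overlaps this pair's own spacer and is the write target
      if (strands[i5] == "+") { src <- i5; dst <- i3 } else { src <- i3; dst <- i5 }
      tpos <- region_positions(dst)
      minus <- strands[dst] == "-"
      igs_lo <- gene_end[i5]; igs_hi <- gene_start[i3]
      if (igs_hi < igs_lo) igs_hi <- igs_hi + L  # wrap pair
      igs_set <- if (igs_hi > igs_lo) seq.int(igs_lo, igs_hi - 1L) %% L
                 else integer(0)
      mut_idx <- which((tpos %% L) %in% igs_set)
      copy_idx <- mut_idx
      head_ok <- types[dst] != "CDS" ||
        (types[src] == "CDS" && types[dst] == "CDS")
      if (head_ok) {
        head_len <- if (types[dst] == "CDS") 48L else downstream
        copy_idx <- c(copy_idx, upstream + seq_len(head_len))
      }
      if (length(copy_idx) < 10L) next
      src_region <- read_region(src)
      dst_region <- read_region(dst)
      cand <- dst_region
      cand[copy_idx] <- src_region[copy_idx]
      e_src <- fold_e(src_region)
      e_cand <- fold_e(cand)
      r <- cor0(e_src, e_cand)
      iter <- 0L
      while (r > target_r + 0.05 && iter < max_iter && length(mut_idx) >= 2L) {
        pick <- pick_near(mut_idx, 2L)
        prop <- cand
        prop[pick] <- rand_bases(length(pick), op_gc)
        e_prop <- refold(prop, e_cand, pick)
        r2 <- cor0(e_src, e_prop)
        if (r2 >= target_r - 0.05) { cand <- prop; e_cand <- e_prop; r <- r2 }
        iter <- iter + 1L
      }
      ## the copy inherits the source's base composition; squeeze the spacer
      ## back toward the configured OP GC while staying inside the r band
      gc_iter <- 0L; rejected <- 0L
      repeat {
        gc_pool <- mut_idx[cand[mut_idx] %in% c("G", "C")]
        gc_now <- length(gc_pool) / max(1L, length(mut_idx))
        if (gc_now <= op_gc + 0.05 || gc_iter >= 40L || rejected >= 8L ||
            length(gc_pool) < 3L)
          break
        pick <- pick_near(gc_pool, 5L)
        prop <- cand
        prop[pick] <- sample(c("A", "T"), length(pick), replace = TRUE)
        e_prop <- refold(prop, e_cand, pick)
        r2 <- cor0(e_src, e_prop)
        if (r2 >= target_r - 0.05 && r2 <= max(r, target_r + 0.05)) {
          cand <- prop; e_cand <- e_prop; r <- r2; rejected <- 0L
        } else rejected <- rejected + 1L
        gc_iter <- gc_iter + 1L
      }
      achieved <- c(achieved, r)
      write_v <- if (minus) complement_chars(cand) else cand
      genome[gidx(tpos)] <- write_v
    }
  }
  list(genome = genome, achieved = achieved)
}

#' Shuffled-block reference panel for the conservation feature
#'
#' Emits rearranged copies of a genome's gene order: each circular adjacency
#' is broken independently with probability `rearrangement_rate`, the
#' resulting blocks are shuffled, and the genes are re-laid with uniform
#' spacers. At rate 0 every adjacency (including the wrap) is conserved; at
#' rate 1 conservation drops to the chance adjacency level.
#'
#' @param x a `plastome` (e.g. from [simulate_plastome()]).
#' @param n_genomes number of reference genomes.
#' @param rearrangement_rate per-adjacency break probability in `[0, 1]`.
#' @param seed integer seed.
#' @return list of `plastome` objects.
#' @export
make_reference_panel <- function(x, n_genomes = 5L, rearrangement_rate = 0.2,
                                 seed = 1L) {
  stopifnot(rearrangement_rate >= 0, rearrangement_rate <= 1)
  set.seed(seed)
  g <- x$genes
  n <- nrow(g)
  lapply(seq_len(n_genomes), function(k) {
    broken <- runif(n) < rearrangement_rate   # adjacency i -> i+1 (n wraps)
    ord <- if (!any(broken)) seq_len(n) else {
      cuts <- which(broken)
      rot <- c(seq.int(cuts[1L] + 1L, n), seq_len(cuts[1L]))
      block_id <- cumsum(c(TRUE, broken[rot[-n]]))
      blocks <- split(rot, block_id)
      unlist(blocks[sample.int(length(blocks))], use.names = FALSE)
    }
    len <- g$end[ord] - g$start[ord]
    start <- cumsum(c(0L, head(len + 50L, -1L)))
    genes <- data.frame(gene_id = g$gene_id[ord], gene_type = g$gene_type[ord],
                        strand = g$strand[ord], start = start,
                        end = start + len, product = NA_character_,
                        stringsAsFactors = FALSE)
    plastome(sprintf("%s_ref%02d", x$genome_id, k),
             strrep("A", sum(len + 50L)), genes, circular = TRUE)
  })
}

#' Write a simulation to disk
#'
#' Emits the annotated genome as GenBank, the pair truth table as TSV, and
#' the configuration as JSON for provenance.
#'
#' @param sim a `sim_plastome`.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genbank(sim$plastome, file.path(dir, "genome.gbk"))
  write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cfg <- sim$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
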