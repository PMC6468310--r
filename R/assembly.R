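## Concatenate classified adjacent pairs into maximal operons and summarise
## genome-level operon structure.

#' Assemble an operon map from pair predictions
#'
#' Maximal runs of pairs labelled 1 are concatenated into multi-gene
#' operons; genes with no positive flanking pair become monocistrons. On a
#' circular genome a run crossing the origin forms a single operon (flagged
#' `wraps_origin`), and a genome whose pairs are all positive yields one
#' operon holding every gene. Pairs present in the genome but missing from
#' `predictions` are treated as label 0 with a warning; predictions naming
#' unknown pairs are an error.
#'
#' @param predictions data.frame with `pair_id` and `label` (and optionally
#'   `score`) as produced by [predict.operon_classifier()], or a truth table
#'   from [simulate_plastome()].
#' @param x the `plastome` the predictions refer to.
#' @return object of class `operon_map`: `genome_id`, `operons` (list of
#'   gene_id vectors in genomic order), `pair_scores`, `gene_types`,
#'   `flags` (per-operon strand consistency and origin wrap).
#' @export
assemble_operons <- function(predictions, x) {
  pairs <- suppressWarnings(enumerate_adjacent_pairs(x))
  unknown <- setdiff(predictions$pair_id, pairs$pair_id)
  if (length(unknown))
    stop2("predictions reference unknown pairs: ",
          paste(head(unknown, 5L), collapse = ", "))
  idx <- match(pairs$pair_id, predictions$pair_id)
  lab <- as.integer(predictions$label[idx])
  if (anyNA(lab)) {
    warning(sum(is.na(lab)), " pair(s) without a prediction treated as label 0")
    lab[is.na(lab)] <- 0L
  }
  score <- if (!is.null(predictions$score)) predictions$score[idx] else
    rep(NA_real_, length(lab))
  g <- x$genes
  n <- nrow(g)
  circ <- x$circular

  if (circ && all(lab == 1L)) {
    operons <- list(g$gene_id)
  } else if (circ) {
    boundaries <- which(lab == 0L)           # pair i joins gene i and i+1
    starts <- (boundaries %% n) + 1L         # operon starts after a boundary
    starts <- sort(starts)
    operons <- lapply(seq_along(starts), function(k) {
      from <- starts[k]
      to_excl <- if (k < length(starts)) starts[k + 1L] else starts[1L] + n
      idxs <- ((seq.int(from, to_excl - 1L) - 1L) %% n) + 1L
      g$gene_id[idxs]
    })
    ## order operons by their first gene's genomic position
    operons <- operons[order(vapply(operons, function(op)
      g$start[match(op[1L], g$gene_id)], numeric(1)))]
  } else {
    breaks <- c(0L, which(lab == 0L), n)
    operons <- lapply(seq_len(length(breaks) - 1L), function(k) {
      g$gene_id[(breaks[k] + 1L):breaks[k + 1L]]
    })
  }

  flags <- data.frame(
    operon_id = sprintf("operon_%03d", seq_along(operons)),
    n_genes = vapply(operons, length, integer(1)),
    strand_consistent = vapply(operons, function(op)
      length(unique(g$strand[match(op, g$gene_id)])) == 1L, logical(1)),
    wraps_origin = vapply(operons, function(op) {
      pos <- match(op, g$gene_id)
      any(diff(pos) < 0L)                   # index order wraps past gene n
    }, logical(1)),
    stringsAsFactors = FALSE)

  structure(list(genome_id = x$genome_id,
                 operons = operons,
                 pair_scores = data.frame(pair_id = pairs$pair_id,
                                          gene5 = pairs$gene5,
                                          gene3 = pairs$gene3,
                                          label = lab, score = score,
                                          stringsAsFactors = FALSE),
                 gene_types = setNames(g$gene_type, g$gene_id),
                 circular = circ,
                 flags = flags),
            class = "operon_map")
}

#' @export
print.operon_map <- function(x, ...) {
  len <- vapply(x$operons, length, integer(1))
  cat(sprintf("<operon_map> %s: %d transcription units (%d multi-gene, largest %d genes)\n",
              x$genome_id, length(x$operons), sum(len >= 2L), max(len)))
  invisible(x)
}

#' Summarise an operon map
#'
#' A gene counts as "in an operon" only when its transcription unit holds at
#' least two genes; monocistrons are excluded.
#'
#' @param object an `operon_map`.
#' @param ... ignored.
#' @return object of class `summary.operon_map` with the fraction of CDSs
#'   and of all genes found in multi-gene operons, per-class membership
#'   counts, and operon-size tallies.
#' @export
summary.operon_map <- function(object, ...) {
  len <- vapply(object$operons, length, integer(1))
  in_operon <- unlist(object$operons[len >= 2L], use.names = FALSE)
  types <- object$gene_types
  all_genes <- names(types)
  classes <- sort(unique(unname(types)))
  class_counts <- data.frame(
    class = classes,
    in_operon = vapply(classes, function(cl)
      sum(types[in_operon] == cl), integer(1)),
    total = vapply(classes, function(cl) sum(types == cl), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  out <- list(
    genome_id = object$genome_id,
    n_operons = length(object$operons),
    n_multi = sum(len >= 2L),
    frac_cds_in_operons =
      if (any(types == "CDS"))
        sum(types[in_operon] == "CDS") / sum(types == "CDS") else NA_real_,
    frac_genes_in_operons = length(in_operon) / length(all_genes),
    class_counts = class_counts,
    size_table = table(len))
  class(out) <- "summary.operon_map"
  out
}

#' @export
print.summary.operon_map <- function(x, ...) {
  cat(sprintf("Operon map of %s: %d units (%d polycistronic)\n",
              x$genome_id, x$n_operons, x$n_multi))
  cat(sprintf("  CDSs in operons:  %.1f%%\n", 100 * x$frac_cds_in_operons))
  cat(sprintf("  all genes in operons: %.1f%%\n", 100 * x$frac_genes_in_operons))
  print(x$class_counts, row.names = FALSE)
  invisible(x)
}

#' Gene-class enrichment among operon genes
#'
#' Feeds the per-class operon membership counts of a map into
#' [enrichment_index()] and [hypergeometric_enrichment()].
#'
#' @param map an `operon_map`.
#' @return data.frame with one row per gene class: counts, enrichment index
#'   and hypergeometric P-value.
#' @export
operon_class_enrichment <- function(map) {
  s <- summary(map)
  cc <- s$class_counts
  N <- sum(cc$in_operon); M <- sum(cc$total)
  if (N == 0L) stop2("no genes in multi-gene operons")
  data.frame(
    class = cc$class, X = cc$in_operon, N = N, K = cc$total, M = M,
    enrichment_index = enrichment_index(cc$in_operon, N, cc$total, M),
    p_value = hypergeometric_enrichment(cc$in_operon, N, cc$total, M),
    stringsAsFactors = FALSE)
}

## -- writers ----------------------------------------------------------------

#' Write an operon map as TSV
#'
#' One row per gene: genome, operon id, gene id, position in operon, and the
#' vote score of the pair joining the gene to its upstream neighbour.
#'
#' @param map an `operon_map`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_operon_tsv <- function(map, path) {
  up_score <- setNames(map$pair_scores$score, map$pair_scores$gene3)
  rows <- lapply(seq_along(map$operons), function(k) {
    op <- map$operons[[k]]
    data.frame(genome_id = map$genome_id,
               operon_id = map$flags$operon_id[k],
               gene_id = op,
               position_in_operon = seq_along(op),
               pair_score_upstream = unname(up_score[op]),
               stringsAsFactors = FALSE)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  invisible(path)
}

operon_spans <- function(map, x) {
  g <- x$genes
  t(vapply(map$operons, function(op) {
    pos <- match(op, g$gene_id)
    c(start = min(g$start[pos]), end = max(g$end[pos]))
  }, numeric(2)))
}

#' Write an operon map as GFF3 `operon` features
#'
#' Each operon becomes one `operon` feature spanning its member genes
#' (origin-wrapping operons span to the genome end and are flagged in the
#' attributes).
#'
#' @param map an `operon_map`.
#' @param x the underlying `plastome` (for coordinates).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_operon_gff3 <- function(map, x, path) {
  g <- x$genes
  spans <- operon_spans(map, x)
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", x$genome_id, genome_length(x)))
  for (k in seq_along(map$operons)) {
    op <- map$operons[[k]]
    strands <- unique(g$strand[match(op, g$gene_id)])
    attr <- sprintf("ID=%s;genes=%s%s", map$flags$operon_id[k],
                    paste(op, collapse = ","),
                    if (map$flags$wraps_origin[k]) ";wraps_origin=true" else "")
    lines <- c(lines, paste(x$genome_id, "plastoperon", "operon",
                            spans[k, 1L] + 1L, spans[k, 2L], ".",
                            if (length(strands) == 1L) strands else ".",
                            ".", attr, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write an operon map as BED12
#'
#' One BED12 record per operon with one block per member gene.
#'
#' @inheritParams write_operon_gff3
#' @return `path`, invisibly.
#' @export
write_operon_bed12 <- function(map, x, path) {
  g <- x$genes
  lines <- character(0)
  for (k in seq_along(map$operons)) {
    op <- map$operons[[k]]
    pos <- match(op, g$gene_id)
    pos <- pos[order(g$start[pos])]
    chrom_start <- min(g$start[pos]); chrom_end <- max(g$end[pos])
    strands <- unique(g$strand[pos])
    sizes <- g$end[pos] - g$start[pos]
    starts <- g$start[pos] - chrom_start
    lines <- c(lines, paste(
      x$genome_id, chrom_start, chrom_end, map$flags$operon_id[k],
      round(1000 * mean(map$pair_scores$score[
        map$pair_scores$gene3 %in% op], na.rm = TRUE)) ,
      if (length(strands) == 1L) strands else ".",
      chrom_start, chrom_end, "0,0,0", length(op),
      paste(sizes, collapse = ","), paste(starts, collapse = ","),
      sep = "\t"))
  }
  lines <- gsub("\tNaN\t", "\t0\t", lines)
  writeLines(lines, path)
  invisible(path)
}
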