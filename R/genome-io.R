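## Annotated plastome container, GenBank / GFF3 parsing, adjacent-pair
## enumeration. Coordinates are 0-based half-open internally; GenBank's
## 1-based inclusive convention is converted on read and write.

#' Construct a plastome annotation object
#'
#' Internal constructor used by the parsers and the simulator. `genes` must
#' contain columns `gene_id`, `gene_type` (CDS/tRNA/rRNA/other), `strand`
#' (+/-), `start`, `end` (0-based half-open) and optionally `product`,
#' `parts` (list of 0-based half-open part matrices for joined locations) and
#' `non_canonical` (CDS whose exonic length is not a codon multiple).
#'
#' @param genome_id character scalar.
#' @param sequence nucleotide string; normalised to upper-case ACGTN (U -> T).
#' @param genes data.frame of gene records.
#' @param circular logical; plastomes are circular by default.
#' @return an object of class `plastome`.
#' @export
plastome <- function(genome_id, sequence, genes, circular = TRUE) {
  sequence <- normalize_seq(sequence)
  stopifnot(is.data.frame(genes))
  if (is.null(genes$product)) genes$product <- NA_character_
  if (is.null(genes$non_canonical)) genes$non_canonical <- FALSE
  if (is.null(genes$parts)) {
    genes$parts <- lapply(seq_len(nrow(genes)), function(i)
      cbind(start = genes$start[i], end = genes$end[i]))
  }
  genes <- genes[order(genes$start, genes$end), , drop = FALSE]
  rownames(genes) <- NULL
  if (anyDuplicated(genes$gene_id)) {
    dup <- duplicated(genes$gene_id) | duplicated(genes$gene_id, fromLast = TRUE)
    genes$gene_id[dup] <- paste0(genes$gene_id[dup], "_", genes$start[dup] + 1L)
  }
  obj <- structure(
    list(genome_id = genome_id, sequence = sequence,
         circular = isTRUE(circular), genes = genes),
    class = "plastome")
  validate_plastome(obj)
  obj
}

normalize_seq <- function(s) {
  s <- chartr("U", "T", toupper(s))
  gsub("[^ACGTN]", "N", s)
}

#' @export
print.plastome <- function(x, ...) {
  cat(sprintf("<plastome> %s: %s bp (%s), %d genes (%s)\n",
              x$genome_id, format(genome_length(x), big.mark = ","),
              if (x$circular) "circular" else "linear",
              nrow(x$genes),
              paste(sprintf("%d %s", as.integer(table(x$genes$gene_type)),
                            names(table(x$genes$gene_type))), collapse = ", ")))
  invisible(x)
}

#' Genome length in nucleotides
#' @param x a `plastome`.
#' @return integer length.
#' @export
genome_length <- function(x) nchar(x$sequence)

validate_plastome <- function(x) {
  g <- x$genes
  L <- genome_length(x)
  if (nrow(g) == 0L) stop2("plastome '", x$genome_id, "' has no gene features")
  if (any(g$start < 0L | g$start >= L))
    stop2("gene start outside [0, genome length)")
  if (any(g$end <= 0L))
    stop2("gene end must be positive")
  if (anyDuplicated(g$gene_id)) stop2("duplicate gene_id after disambiguation")
  if (!all(g$strand %in% c("+", "-"))) stop2("strand must be '+' or '-'")
  if (!all(g$gene_type %in% c("CDS", "tRNA", "rRNA", "other")))
    stop2("unknown gene_type")
  invisible(TRUE)
}

## -- sequence access (0-based half-open, wraps the origin when circular) ----

seq_window <- function(x, start, end) {
  L <- genome_length(x)
  width <- end - start
  if (width <= 0L) return("")
  if (start >= 0L && end <= L)
    return(substr(x$sequence, start + 1L, end))
  if (!x$circular) {
    start <- max(0L, start); end <- min(L, end)
    if (end <= start) return("")
    return(substr(x$sequence, start + 1L, end))
  }
  if (width >= L) return(x$sequence)
  start <- ((start %% L) + L) %% L
  e <- start + width
  if (e <= L) substr(x$sequence, start + 1L, e)
  else paste0(substr(x$sequence, start + 1L, L), substr(x$sequence, 1L, e - L))
}

revcomp <- function(s) {
  if (nchar(s) == 0L) return(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Spliced gene sequence
#'
#' Concatenates the exonic parts of a gene (in genomic order) and reverse
#' complements the result for minus-strand genes, yielding the coding/mature
#' orientation.
#'
#' @param x a `plastome`.
#' @param gene a `gene_id` or row index into `x$genes`.
#' @return nucleotide string.
#' @export
gene_sequence <- function(x, gene) {
  i <- if (is.character(gene)) match(gene, x$genes$gene_id) else gene
  if (is.na(i)) stop2("unknown gene: ", gene)
  parts <- x$genes$parts[[i]]
  s <- paste0(vapply(seq_len(nrow(parts)), function(k)
    seq_window(x, parts[k, 1L], parts[k, 2L]), character(1)), collapse = "")
  if (x$genes$strand[i] == "-") revcomp(s) else s
}

## -- GenBank ----------------------------------------------------------------

#' Parse an annotated plastome
#'
#' Reads a GenBank flat file, or a GFF3 annotation plus its FASTA sequence,
#' into a [plastome()] object. Gene records are taken from CDS, tRNA and
#' rRNA features; pseudogenes and features without usable coordinates are
#' skipped with a warning. GenBank 1-based inclusive coordinates are
#' converted to the internal 0-based half-open convention.
#'
#' @param path GenBank file, or GFF3 file when `format = "gff3"`.
#' @param format `"genbank"` (default, inferred from extension) or `"gff3"`.
#' @param fasta FASTA file with the genome sequence (GFF3 input only).
#' @param circular logical; used for GFF3 input (GenBank declares it in the
#'   LOCUS line).
#' @return a `plastome`.
#' @export
parse_plastome <- function(path, format = c("auto", "genbank", "gff3"),
                           fasta = NULL, circular = TRUE) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("gff", "gff3")) "gff3" else "genbank"
  }
  if (format == "genbank") parse_genbank(path)
  else parse_gff3(path, fasta, circular = circular)
}

parse_genbank <- function(path) {
  if (!file.exists(path)) stop2("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  li <- grep("^LOCUS", lines)
  if (length(li) == 0L) stop2("not a GenBank record (no LOCUS line): ", path)
  locus <- lines[li[1L]]
  circular <- grepl("circular", locus, ignore.case = TRUE)
  genome_id <- strsplit(trimws(sub("^LOCUS", "", locus)), "\\s+")[[1L]][1L]
  fi <- grep("^FEATURES", lines)
  oi <- grep("^ORIGIN", lines)
  ei <- grep("^//", lines)
  if (length(fi) == 0L || length(oi) == 0L)
    stop2("malformed GenBank record '", genome_id, "': missing FEATURES or ORIGIN")
  seq_end <- if (length(ei)) ei[1L] - 1L else length(lines)
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(lines[(oi[1L] + 1L):seq_end],
                                                  collapse = "")))
  feat <- lines[(fi[1L] + 1L):(oi[1L] - 1L)]

  keys <- substr(feat, 6L, 20L)
  is_new <- trimws(keys) != "" & !startsWith(trimws(feat), "/")
  idx <- which(is_new)
  records <- list()
  skipped <- 0L
  for (k in seq_along(idx)) {
    from <- idx[k]
    to <- if (k < length(idx)) idx[k + 1L] - 1L else length(feat)
    key <- trimws(keys[from])
    if (!key %in% c("CDS", "tRNA", "rRNA")) next
    block <- feat[from:to]
    qual_start <- which(startsWith(trimws(block), "/"))
    qs <- if (length(qual_start)) qual_start[1L] else length(block) + 1L
    loc_lines <- block[seq_len(qs - 1L)]
    loc <- gsub("\\s+", "", paste(c(substr(loc_lines[1L], 22L, nchar(loc_lines[1L])),
                                    trimws(loc_lines[-1L])), collapse = ""))
    quals <- if (qs <= length(block))
      paste(trimws(block[qs:length(block)]), collapse = " ") else ""
    if (grepl("/pseudo\\b|/pseudogene", quals)) { skipped <- skipped + 1L; next }
    parsed <- tryCatch(parse_gb_location(loc), error = function(e) NULL)
    if (is.null(parsed)) { skipped <- skipped + 1L; next }
    gene <- gb_qualifier(quals, "gene") %||% gb_qualifier(quals, "locus_tag") %||%
      paste0(tolower(key), "_", parsed$parts[1L, 1L] + 1L)
    records[[length(records) + 1L]] <- list(
      gene_id = gene, gene_type = key, strand = parsed$strand,
      start = min(parsed$parts[, 1L]), end = max(parsed$parts[, 2L]),
      product = gb_qualifier(quals, "product") %||% NA_character_,
      parts = parsed$parts)
  }
  if (skipped > 0L)
    warning(sprintf("%s: skipped %d pseudogene/uncoordinated feature(s)",
                    genome_id, skipped))
  if (length(records) == 0L)
    stop2("no gene features found in ", path)
  genes <- data.frame(
    gene_id = vapply(records, `[[`, "", "gene_id"),
    gene_type = vapply(records, `[[`, "", "gene_type"),
    strand = vapply(records, `[[`, "", "strand"),
    start = vapply(records, `[[`, 0, "start"),
    end = vapply(records, `[[`, 0, "end"),
    product = vapply(records, `[[`, "", "product"),
    stringsAsFactors = FALSE)
  genes$parts <- lapply(records, `[[`, "parts")
  genes$non_canonical <- genes$gene_type == "CDS" &
    vapply(records, function(r) sum(r$parts[, 2L] - r$parts[, 1L]) %% 3L != 0L,
           logical(1))
  plastome(genome_id, sequence, genes, circular = circular)
}

## location strings: 10..100, complement(10..100), join(1..5,8..20),
## complement(join(...)), partial markers < and > are stripped.
parse_gb_location <- function(loc) {
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
  if (grepl("complement", loc)) {  # join(complement(..),..): uniform strand
    strand <- "-"
    loc <- gsub("complement\\(([^)]*)\\)", "\\1", loc)
  }
  loc <- gsub("[<>]", "", loc)
  pieces <- strsplit(loc, ",", fixed = TRUE)[[1L]]
  parts <- t(vapply(pieces, function(p) {
    nums <- as.integer(strsplit(p, "\\.\\.")[[1L]])
    if (length(nums) == 1L) nums <- c(nums, nums)
    if (anyNA(nums)) stop2("unparseable location piece: ", p)
    c(nums[1L] - 1L, nums[2L])           # to 0-based half-open
  }, integer(2)))
  colnames(parts) <- c("start", "end")
  rownames(parts) <- NULL
  list(strand = strand, parts = parts)
}

gb_qualifier <- function(quals, name) {
  m <- regmatches(quals, regexec(sprintf('/%s="([^"]*)"', name), quals))[[1L]]
  if (length(m) == 2L) return(m[2L])
  m <- regmatches(quals, regexec(sprintf("/%s=([^ /]+)", name), quals))[[1L]]
  if (length(m) == 2L) m[2L] else NULL
}

#' Write a plastome as a GenBank flat file
#'
#' Emits a minimal standards-compliant record (LOCUS with length and
#' topology, one feature per gene with `/gene` and `/product` qualifiers,
#' ORIGIN sequence block). Round-trips through [parse_plastome()].
#'
#' @param x a `plastome`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(x, path) {
  L <- genome_length(x)
  out <- c(sprintf("LOCUS       %-16s %d bp    DNA     %s PLN 01-JAN-2026",
                   x$genome_id, L, if (x$circular) "circular" else "linear"),
           sprintf("DEFINITION  %s plastome annotation.", x$genome_id),
           sprintf("ACCESSION   %s", x$genome_id),
           "FEATURES             Location/Qualifiers",
           sprintf("     source          1..%d", L))
  for (i in seq_len(nrow(x$genes))) {
    g <- x$genes[i, ]
    parts <- x$genes$parts[[i]]
    spans <- sprintf("%d..%d", parts[, 1L] + 1L, parts[, 2L])
    loc <- if (length(spans) > 1L) sprintf("join(%s)", paste(spans, collapse = ","))
           else spans
    if (g$strand == "-") loc <- sprintf("complement(%s)", loc)
    out <- c(out,
             sprintf("     %-15s %s", g$gene_type, loc),
             sprintf('                     /gene="%s"', g$gene_id))
    if (!is.na(g$product))
      out <- c(out, sprintf('                     /product="%s"', g$product))
  }
  out <- c(out, "ORIGIN")
  s <- tolower(x$sequence)
  starts <- seq(1L, nchar(s), by = 60L)
  for (st in starts) {
    chunk <- substr(s, st, min(st + 59L, nchar(s)))
    blocks <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    out <- c(out, sprintf("%9d %s", st, paste(blocks, collapse = " ")))
  }
  out <- c(out, "//")
  writeLines(out, path)
  invisible(path)
}

## -- GFF3 + FASTA -----------------------------------------------------------

parse_gff3 <- function(gff, fasta, circular = TRUE) {
  if (is.null(fasta)) stop2("GFF3 input requires a FASTA sequence file")
  gr <- rtracklayer::import(gff)
  df <- as.data.frame(gr)
  keep <- toupper(df$type) %in% c("CDS", "TRNA", "RRNA")
  df <- df[keep, , drop = FALSE]
  if (nrow(df) == 0L) stop2("no CDS/tRNA/rRNA features found in ", gff)
  sset <- Biostrings::readDNAStringSet(fasta)
  sequence <- as.character(sset[[1L]])
  genome_id <- strsplit(names(sset)[1L], "\\s+")[[1L]][1L]
  pick <- function(...) {
    for (nm in c(...)) if (!is.null(df[[nm]])) return(as.character(df[[nm]]))
    rep(NA_character_, nrow(df))
  }
  ids <- pick("gene", "Name", "ID", "locus_tag")
  ids[is.na(ids)] <- paste0("feature_", which(is.na(ids)))
  type_map <- c(CDS = "CDS", TRNA = "tRNA", RRNA = "rRNA")
  df$gene_key <- ids
  keys <- unique(ids)
  records <- lapply(keys, function(k) {
    rows <- df[df$gene_key == k, , drop = FALSE]
    parts <- cbind(start = rows$start - 1L, end = rows$end)
    parts <- parts[order(parts[, 1L]), , drop = FALSE]
    list(gene_id = k,
         gene_type = unname(type_map[toupper(as.character(rows$type[1L]))]),
         strand = if (as.character(rows$strand[1L]) %in% c("+", "-"))
           as.character(rows$strand[1L]) else "+",
         start = min(parts[, 1L]), end = max(parts[, 2L]),
         product = NA_character_, parts = parts)
  })
  genes <- data.frame(
    gene_id = vapply(records, `[[`, "", "gene_id"),
    gene_type = vapply(records, `[[`, "", "gene_type"),
    strand = vapply(records, `[[`, "", "strand"),
    start = vapply(records, `[[`, 0, "start"),
    end = vapply(records, `[[`, 0, "end"),
    product = vapply(records, `[[`, "", "product"),
    stringsAsFactors = FALSE)
  genes$parts <- lapply(records, `[[`, "parts")
  genes$non_canonical <- genes$gene_type == "CDS" &
    vapply(records, function(r) sum(r$parts[, 2L] - r$parts[, 1L]) %% 3L != 0L,
           logical(1))
  plastome(genome_id, sequence, genes, circular = circular)
}

#' Write the normalised gene table as TSV
#'
#' @param x a `plastome`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(x, path) {
  g <- x$genes[, c("gene_id", "gene_type", "strand", "start", "end")]
  g <- cbind(genome_id = x$genome_id, g)
  write.table(g, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## -- adjacent pairs ---------------------------------------------------------

#' Enumerate adjacent gene pairs
#'
#' Lists every ordered pair of neighbouring genes in genomic order: n pairs
#' for n genes on a circular genome (the wrap pair last->first is emitted
#' once, flagged `wraps_origin`), n-1 on a linear genome. The intergenic
#' spacer (IGS) is the half-open interval between the upstream gene's end and
#' the downstream gene's start; its signed length is negative for overlapping
#' genes. `pair_group` is `"CDS"` when both members are coding sequences and
#' `"mixed"` otherwise; opposite-strand neighbours are enumerated and carry
#' `same_strand = FALSE`.
#'
#' @param x a `plastome`.
#' @return data.frame of class `gene_pairs` with one row per adjacent pair,
#'   ordered by the upstream gene's start.
#' @export
enumerate_adjacent_pairs <- function(x) {
  g <- x$genes
  n <- nrow(g)
  empty <- data.frame(pair_id = character(), gene5 = character(),
                      gene3 = character(), pair_group = character(),
                      same_strand = logical(), wraps_origin = logical(),
                      igs_start = integer(), igs_end = integer(),
                      igs_length = integer(), stringsAsFactors = FALSE)
  if (n < 2L) {
    warning("fewer than two genes: no adjacent pairs")
    return(as_gene_pairs(empty, x))
  }
  L <- genome_length(x)
  if (x$circular) { i5 <- seq_len(n); i3 <- c(seq_len(n)[-1L], 1L) }
  else { i5 <- seq_len(n - 1L); i3 <- i5 + 1L }
  wraps <- x$circular & i5 == n
  igs_start <- g$end[i5]
  igs_end <- g$start[i3] + ifelse(wraps, L, 0L)
  out <- data.frame(
    pair_id = paste(g$gene_id[i5], g$gene_id[i3], sep = "|"),
    gene5 = g$gene_id[i5], gene3 = g$gene_id[i3],
    pair_group = ifelse(g$gene_type[i5] == "CDS" & g$gene_type[i3] == "CDS",
                        "CDS", "mixed"),
    same_strand = g$strand[i5] == g$strand[i3],
    wraps_origin = wraps,
    igs_start = as.integer(igs_start), igs_end = as.integer(igs_end),
    igs_length = as.integer(igs_end - igs_start),
    stringsAsFactors = FALSE)
  as_gene_pairs(out, x)
}

as_gene_pairs <- function(df, x) {
  attr(df, "genome_id") <- x$genome_id
  attr(df, "genome_length") <- genome_length(x)
  attr(df, "circular") <- x$circular
  class(df) <- c("gene_pairs", "data.frame")
  df
}

#' Signed intergenic distance of adjacent pairs
#'
#' `gene3.start - gene5.end`, modulo the genome length for the wrap pair;
#' negative values indicate overlapping genes.
#'
#' @param pairs a `gene_pairs` data.frame from [enumerate_adjacent_pairs()].
#' @return integer vector of signed distances (nt).
#' @export
intergenic_distance <- function(pairs) pairs$igs_end - pairs$igs_start

#' Intergenic spacer sequence of one pair
#'
#' @param x a `plastome`.
#' @param pair one row of a `gene_pairs` data.frame.
#' @return forward-strand spacer sequence; `""` when the genes overlap or
#'   abut.
#' @export
igs_sequence <- function(x, pair) {
  if (pair$igs_length <= 0L) return("")
  seq_window(x, pair$igs_start, pair$igs_end)
}
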