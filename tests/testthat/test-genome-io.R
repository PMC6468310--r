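test_that("hand-written GenBank parses with correct coordinates, strands and types", {
  gb <- withr::local_tempfile(fileext = ".gbk")
  write_tiny_genbank(gb)
  pl <- suppressWarnings(parse_plastome(gb))
  expect_s3_class(pl, "plastome")
  expect_true(pl$circular)
  expect_equal(genome_length(pl), 600L)
  g <- pl$genes
  expect_equal(nrow(g), 5L)                  # pseudogene skipped
  expect_equal(g$gene_id, c("psbA", "rbcL", "petB", "trnE", "rrn16"))
  expect_equal(g$gene_type, c("CDS", "CDS", "CDS", "tRNA", "rRNA"))
  ## 1-based inclusive 11..100 -> 0-based half-open [10, 100)
  expect_equal(g$start, c(10, 120, 230, 350, 440))
  expect_equal(g$end, c(100, 210, 330, 420, 560))
  expect_equal(g$strand, c("+", "-", "+", "+", "+"))
  ## joined location keeps both exonic parts
  expect_equal(g$parts[[3]], cbind(start = c(230, 300), end = c(290, 330)))
  expect_equal(nchar(gene_sequence(pl, "petB")), 90L)
  ## pseudogene skip is warned about
  expect_warning(parse_plastome(gb), "pseudo")
})

test_that("GenBank writing round-trips through the parser field-for-field", {
  sim <- cached_sim("tiny", sim_config(n_genes = 20L, seed = 4L))
  gb <- withr::local_tempfile(fileext = ".gbk")
  write_genbank(sim$plastome, gb)
  back <- parse_plastome(gb)
  expect_equal(back$genome_id, sim$plastome$genome_id)
  expect_equal(back$sequence, sim$plastome$sequence)
  expect_true(back$circular)
  for (col in c("gene_id", "gene_type", "strand", "start", "end"))
    expect_equal(back$genes[[col]], sim$plastome$genes[[col]], info = col)
  ## parsing is idempotent: write the parsed copy and parse again
  gb2 <- withr::local_tempfile(fileext = ".gbk")
  write_genbank(back, gb2)
  expect_equal(parse_plastome(gb2)$genes$start, back$genes$start)
})

test_that("an independent GenBank reader agrees on the written record", {
  sim <- cached_sim("tiny", sim_config(n_genes = 20L, seed = 4L))
  gb <- withr::local_tempfile(fileext = ".gbk")
  write_genbank(sim$plastome, gb)
  script <- paste(
    "from Bio import SeqIO",
    sprintf("rec = SeqIO.read('%s', 'genbank')", gb),
    "feats = [f for f in rec.features if f.type in ('CDS','tRNA','rRNA')]",
    "print(len(rec.seq))",
    "for f in feats:",
    "    print(int(f.location.start), int(f.location.end), f.location.strand)",
    sep = "\n")
  out <- system2("python", "-", input = script, stdout = TRUE)
  expect_equal(as.integer(out[1]), genome_length(sim$plastome))
  coords <- do.call(rbind, lapply(out[-1], function(l)
    as.integer(strsplit(l, " ")[[1]])))
  g <- sim$plastome$genes
  expect_equal(coords[, 1], g$start)
  expect_equal(coords[, 2], g$end)
  expect_equal(ifelse(coords[, 3] == 1, "+", "-"), g$strand)
})

test_that("GFF3 + FASTA input yields the same annotation as GenBank", {
  sim <- cached_sim("tiny", sim_config(n_genes = 20L, seed = 4L))
  pl <- sim$plastome
  gff <- withr::local_tempfile(fileext = ".gff3")
  fa <- withr::local_tempfile(fileext = ".fasta")
  g <- pl$genes
  writeLines(c("##gff-version 3",
               sprintf("##sequence-region %s 1 %d", pl$genome_id,
                       genome_length(pl)),
               sprintf("%s\ttest\t%s\t%d\t%d\t.\t%s\t.\tID=%s;gene=%s",
                       pl$genome_id, g$gene_type, g$start + 1L, g$end,
                       g$strand, g$gene_id, g$gene_id)), gff)
  writeLines(c(paste0(">", pl$genome_id), pl$sequence), fa)
  back <- parse_plastome(gff, format = "gff3", fasta = fa)
  expect_equal(back$genes$gene_id, g$gene_id)
  expect_equal(back$genes$start, g$start)
  expect_equal(back$genes$end, g$end)
  expect_equal(back$genes$strand, g$strand)
  expect_equal(back$genes$gene_type, g$gene_type)
  expect_equal(back$sequence, pl$sequence)
})

test_that("adjacent pairs: counts, ordering, groups and wrap pair", {
  pl <- toy_plastome(starts = c(0, 150, 400), ends = c(100, 300, 480),
                     types = c("CDS", "CDS", "tRNA"), L = 530L)
  pairs <- enumerate_adjacent_pairs(pl)
  expect_equal(nrow(pairs), 3L)              # circular: n pairs for n genes
  expect_equal(pairs$gene5, c("g01", "g02", "g03"))
  expect_equal(pairs$gene3, c("g02", "g03", "g01"))
  expect_equal(pairs$pair_group, c("CDS", "mixed", "mixed"))
  expect_equal(pairs$wraps_origin, c(FALSE, FALSE, TRUE))
  expect_equal(intergenic_distance(pairs), c(50L, 100L, 50L))

  lin <- toy_plastome(starts = c(0, 150, 400), ends = c(100, 300, 480),
                      L = 530L, circular = FALSE)
  expect_equal(nrow(enumerate_adjacent_pairs(lin)), 2L)

  single <- toy_plastome(starts = 0, ends = 90)
  expect_warning(p0 <- enumerate_adjacent_pairs(single), "fewer than two")
  expect_equal(nrow(p0), 0L)
})

test_that("overlapping genes give negative spacer length and empty spacer sequence", {
  pl <- toy_plastome(starts = c(0, 90), ends = c(100, 200), L = 260L)
  pairs <- enumerate_adjacent_pairs(pl)
  expect_equal(pairs$igs_length[1], -10L)
  expect_equal(igs_sequence(pl, pairs[1, ]), "")
})

test_that("wrap-pair spacer length uses modular arithmetic", {
  pl <- toy_plastome(starts = c(20, 14900), ends = c(120, 15000), L = 15000L)
  pairs <- enumerate_adjacent_pairs(pl)
  wrap <- pairs[pairs$wraps_origin, ]
  expect_equal(wrap$igs_length, 20L)
  expect_equal(nchar(igs_sequence(pl, wrap)), 20L)
})

test_that("every spacer nucleotide lies outside both member genes", {
  sim <- cached_sim("tiny", sim_config(n_genes = 20L, seed = 4L))
  pl <- sim$plastome
  pairs <- enumerate_adjacent_pairs(pl)
  L <- genome_length(pl)
  gene_cover <- rep(FALSE, L)
  for (i in seq_len(nrow(pl$genes)))
    gene_cover[(pl$genes$start[i]:(pl$genes$end[i] - 1L)) + 1L] <- TRUE
  for (k in seq_len(nrow(pairs))) {
    p <- pairs[k, ]
    if (p$igs_length <= 0L) next
    pos <- (seq.int(p$igs_start, p$igs_end - 1L) %% L) + 1L
    expect_false(any(gene_cover[pos]), label = p$pair_id)
  }
})

test_that("duplicate gene names are disambiguated by coordinates", {
  pl <- toy_plastome(starts = c(0, 200), ends = c(100, 300), L = 400L,
                     ids = c("trnI", "trnI"))
  expect_equal(pl$genes$gene_id, c("trnI_1", "trnI_201"))
})
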