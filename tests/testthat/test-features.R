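test_that("GC content: worked values, N handling, undefined cases, RC invariance", {
  expect_equal(gc_content("ATGC"), 0.5)
  expect_equal(gc_content("GGCC"), 1.0)
  expect_equal(gc_content("GCNN"), 1.0)      # N excluded from both sides
  expect_true(is.na(gc_content("")))
  expect_true(is.na(gc_content("NNNN")))
  ## binomial sampling bound at per-site GC probability 0.3
  set.seed(31)
  s <- paste(sample(c("G", "C", "A", "T"), 10000, replace = TRUE,
                    prob = c(0.15, 0.15, 0.35, 0.35)), collapse = "")
  expect_lt(abs(gc_content(s) - 0.30), 0.02)
  ## gc(revcomp(s)) == gc(s) for random sequences
  set.seed(32)
  for (i in 1:20) {
    r <- paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE),
               collapse = "")
    rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(r, "")[[1]]),
                                       collapse = ""))
    expect_equal(gc_content(rc), gc_content(r))
  }
})

test_that("5' region extraction is strand-aware and re-locatable by exact match", {
  sim <- cached_sim("tiny", sim_config(n_genes = 20L, seed = 4L))
  pl <- sim$plastome
  for (id in pl$genes$gene_id[c(1, 5, 12)]) {
    u <- extract_utr5(pl, id, upstream = 100L, downstream = 50L)
    expect_equal(nchar(u), 150L)
    g <- pl$genes[match(id, pl$genes$gene_id), ]
    ## the downstream part of the window is the gene's own transcript start
    expect_equal(substr(u, 101L, 150L),
                 substr(gene_sequence(pl, id), 1L, 50L), info = id)
  }
  ## plus-strand gene starting at 500 of a linear genome: region [400, 550)
  lin <- toy_plastome(starts = c(0, 500), ends = c(90, 800), L = 900L,
                      circular = FALSE)
  expect_equal(extract_utr5(lin, "g02"),
               substr(lin$sequence, 401L, 550L))
  ## minus-strand gene with 5' end at 800: reverse complement of [750, 900)
  neg <- toy_plastome(starts = c(0, 500), ends = c(90, 800), L = 950L,
                      strands = c("+", "-"), circular = FALSE)
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  expect_equal(extract_utr5(neg, "g02"), rc(substr(neg$sequence, 751L, 900L)))
})

test_that("profile similarity: identity, anti-correlation, shift invariance, symmetry", {
  p <- function(e) structure(list(energies = e, window = 40L, step = 1L,
                                  anchor = ""), class = "folding_profile")
  e <- c(-5, -9, -3, -7, -1, -6)
  expect_equal(profile_similarity(p(e), p(e)), 1.0)
  expect_equal(profile_similarity(p(e), p(-e - 2)), -1.0)
  q <- c(-4, -2, -8, -5, -3, -9)
  expect_equal(profile_similarity(p(e), p(q)),
               profile_similarity(p(q), p(e)))
  expect_equal(profile_similarity(p(e + 3), p(q + 3)),
               profile_similarity(p(e), p(q)))
  expect_true(is.na(profile_similarity(p(e), p(rep(-2, 6)))))   # constant
  expect_true(is.na(profile_similarity(p(e[1:2]), p(q[1:2]))))  # < 3 windows
})

test_that("independent random sequences give profile correlations centred on zero", {
  ## step-1 profiles of neighbouring windows share 39/40 nt, so the null r
  ## of two short profiles is wide (few effective degrees of freedom) but
  ## must be centred on zero and symmetric
  set.seed(77)
  rs <- replicate(60, {
    s1 <- paste(sample(c("A", "C", "G", "T"), 150, TRUE), collapse = "")
    s2 <- paste(sample(c("A", "C", "G", "T"), 150, TRUE), collapse = "")
    profile_similarity(folding_profile(s1), folding_profile(s2))
  })
  expect_lt(abs(mean(rs)), 0.15)
  ## at window-spacing where profile points are independent, the null r
  ## concentrates: ~99 windows of step 20 over 2 kb
  rs2 <- replicate(30, {
    s1 <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
    s2 <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
    profile_similarity(folding_profile(s1, step = 20L),
                       folding_profile(s2, step = 20L))
  })
  expect_gte(mean(abs(rs2) < 0.3), 0.9)
})

test_that("position-wise folding margins equal a brute-force loop", {
  p <- function(e) structure(list(energies = e, window = 40L, step = 1L,
                                  anchor = ""), class = "folding_profile")
  ## identical profiles -> all margins 0
  m0 <- position_margin_profile(list(p(c(-1, -2, -3))), list(p(c(-1, -2, -3))))
  expect_equal(m0$mean_abs_margin, c(0, 0, 0))
  ## constant offsets 1 and 3 kcal/mol -> margin 2 everywhere
  m2 <- position_margin_profile(list(p(c(-5, -6)), p(c(-4, -8))),
                                list(p(c(-6, -7)), p(c(-7, -11))))
  expect_equal(m2$mean_abs_margin, c(2, 2))
  ## random case against explicit double loop
  set.seed(5)
  p5 <- lapply(1:4, function(i) p(rnorm(7, -8)))
  p3 <- lapply(1:4, function(i) p(rnorm(7, -8)))
  got <- position_margin_profile(p5, p3)$mean_abs_margin
  want <- vapply(1:7, function(pos)
    mean(vapply(1:4, function(i)
      abs(p5[[i]]$energies[pos] - p3[[i]]$energies[pos]), numeric(1))),
    numeric(1))
  expect_equal(got, want)
})

test_that("RSCU distance matches a hand-computed two-family toy and is a metric", {
  ## protein M-F-K with fully disjoint synonymous codons:
  ## a: TTT (F), AAA (K); b: TTC, AAG. RSCU = 2 for the used codon of each
  ## two-codon family, 0 for the unused one -> distance sqrt(4 * 2^2) = 4
  a <- "ATGTTTAAATAA"
  b <- "ATGTTCAAGTAA"
  expect_equal(length(rscu(a)), 59L)
  expect_equal(unname(rscu(a)[c("TTT", "TTC", "AAA", "AAG")]), c(2, 0, 2, 0))
  expect_equal(codon_usage_distance(a, b), 4)
  expect_equal(codon_usage_distance(a, a), 0)
  set.seed(8)
  for (i in 1:5) {
    c1 <- paste0("ATG", paste(sample(c("GCT", "GCC", "AAA", "TTT", "GGA"),
                                     30, TRUE), collapse = ""), "TAA")
    c2 <- paste0("ATG", paste(sample(c("GCA", "GCG", "AAG", "TTC", "GGT"),
                                     30, TRUE), collapse = ""), "TAA")
    expect_equal(codon_usage_distance(c1, c2), codon_usage_distance(c2, c1))
  }
  expect_error(rscu("ATGAA"), "divisible by 3")
})

test_that("GRAVY margin matches the published hydropathy scale and is codon-blind", {
  ## M,I,I vs M,D,D: (1.9+4.5+4.5)/3 - (1.9-3.5-3.5)/3 = 16/3
  expect_equal(gravy_margin("ATGATTATTTAA", "ATGGATGATTAA"), 16 / 3)
  expect_equal(gravy_margin("ATGATTATTTAA", "ATGATTATTTAA"), 0)
  ## synonymous recoding (ATT -> ATC, both Ile) leaves the margin unchanged
  expect_equal(gravy_margin("ATGATCATCTAA", "ATGGATGATTAA"), 16 / 3)
  expect_error(gravy("ATGTAAATTTAA"), "internal stop")
})

test_that("pair conservation equals a brute-force bigram scan on shuffled panels", {
  sim <- cached_sim("tiny", sim_config(n_genes = 20L, seed = 4L))
  pl <- sim$plastome
  refs <- make_reference_panel(pl, n_genomes = 6L, rearrangement_rate = 0.4,
                               seed = 2L)
  pairs <- enumerate_adjacent_pairs(pl)
  brute <- function(pair) {
    mean(vapply(refs, function(ref) {
      ids <- tolower(ref$genes$gene_id)
      st <- ref$genes$strand
      n <- length(ids)
      hit <- FALSE
      for (i in seq_len(n)) {
        j <- if (i == n) 1L else i + 1L
        g <- pl$genes
        s5 <- g$strand[match(pair$gene5, g$gene_id)]
        s3 <- g$strand[match(pair$gene3, g$gene_id)]
        same_rel5 <- (st[i] == s5) == (st[j] == s3)
        fl <- function(s) ifelse(s == "+", "-", "+")
        same_rel3 <- (st[i] == fl(s3)) == (st[j] == fl(s5))
        if ((ids[i] == tolower(pair$gene5) && ids[j] == tolower(pair$gene3) &&
             same_rel5) ||
            (ids[i] == tolower(pair$gene3) && ids[j] == tolower(pair$gene5) &&
             same_rel3)) hit <- TRUE
      }
      hit
    }, logical(1)))
  }
  for (k in c(1, 5, 9, 14)) {
    expect_equal(pair_conservation(pairs[k, ], pl, refs), brute(pairs[k, ]),
                 label = pairs$pair_id[k])
  }
  ## a pair of genes that never co-occur adjacently
  fake <- pairs[1, ]
  fake$gene5 <- pl$genes$gene_id[1]; fake$gene3 <- pl$genes$gene_id[10]
  expect_equal(pair_conservation(fake, pl,
                                 make_reference_panel(pl, 4L, 0, seed = 3L)),
               0)
})

test_that("feature matrix honours the CDS/mixed schema and is deterministic", {
  sim <- cached_sim("tiny", sim_config(n_genes = 20L, seed = 4L))
  feats <- cached_features("tiny", sim)
  expect_true(all(c("igs_length", "igs_gc", "cds_gc_5", "cds_gc_3",
                    "gc_margin", "same_strand", "fold_profile_pearson",
                    "fold_profile_mean_abs_margin", "cub_distance",
                    "gravy_margin") %in% names(feats)))
  mixed <- feats$pair_group == "mixed"
  expect_true(any(mixed))
  ## CDS-only features are absent (NA), not zero-filled, for mixed pairs
  expect_true(all(is.na(feats$cub_distance[mixed])))
  expect_true(all(is.na(feats$gravy_margin[mixed])))
  expect_true(all(!is.na(feats$cub_distance[!mixed])))
  ## fractions stay in [0, 1], correlations in [-1, 1]
  expect_true(all(feats$igs_gc >= 0 & feats$igs_gc <= 1, na.rm = TRUE))
  expect_true(all(abs(feats$fold_profile_pearson) <= 1, na.rm = TRUE))
  ## deterministic re-computation
  again <- compute_pair_features(enumerate_adjacent_pairs(sim$plastome),
                                 sim$plastome)
  expect_identical(feats, again)
})
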