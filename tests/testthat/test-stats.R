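test_that("permutation test: degenerate and censored paths", {
  ## identical constant groups: zero margin can never be significant
  r <- permutation_test(c(2, 2, 2, 2), c(2, 2, 2, 2), n = 200L, seed = 1L)
  expect_equal(r$observed_margin, 0)
  expect_equal(r$p_value, 1)
  expect_false(r$censored)
  ## maximal separation exercises the escalation path and returns a bound
  r2 <- permutation_test(c(0, 0, 0, 0), c(9, 9, 9, 9), n = 1000L, seed = 1L)
  expect_true(r2$censored)
  expect_equal(r2$p_value, 1 / 10000)
  expect_match(r2$bound_string, "^P < ")
  ## never exactly zero
  expect_gt(r2$p_value, 0)
})

test_that("permutation test is invariant to swapping the groups", {
  set.seed(3)
  for (i in 1:5) {
    a <- rnorm(12); b <- rnorm(9, mean = 0.5)
    pa <- permutation_test(a, b, n = 2000L, seed = 100L + i)$p_value
    pb <- permutation_test(b, a, n = 2000L, seed = 100L + i)$p_value
    expect_equal(pa, pb)
  }
})

test_that("empiric P-value: trivial separation, null symmetry, swap complement", {
  expect_equal(empiric_pvalue(rep(10, 60), rep(0, 60), rounds = 200L,
                              seed = 1L), 1.0)
  expect_equal(empiric_pvalue(rep(10, 60), rep(0, 60), rounds = 200L,
                              objective = "less", seed = 1L), 0.0)
  set.seed(4)
  a <- rnorm(300); b <- rnorm(300)
  r <- empiric_pvalue(a, b, rounds = 1000L, seed = 2L)
  expect_lt(abs(r - 0.5), 0.1)
  ## swapping groups maps r -> 1 - r for continuous data
  r1 <- empiric_pvalue(a, b, rounds = 500L, seed = 5L)
  r2 <- empiric_pvalue(b, a, rounds = 500L, seed = 5L)
  expect_lt(abs((1 - r1) - r2), 0.08)
  expect_warning(empiric_pvalue(a, b, rounds = 50L, seed = 1L), "resolution")
})

test_that("enrichment index: worked values, bounds and algebraic identity", {
  expect_equal(enrichment_index(10, 100, 10, 1000), 0.9)
  expect_equal(enrichment_index(1, 100, 100, 1000), -9)
  expect_equal(enrichment_index(5, 50, 100, 1000), 0)     # X/N == K/M
  expect_equal(enrichment_index(0, 100, 10, 1000), -Inf)  # fully depleted
  set.seed(6)
  for (i in 1:50) {
    m <- sample(50:500, 1); k <- sample(1:m, 1)
    n <- sample(1:m, 1); x <- sample(0:min(n, k), 1)
    ei <- enrichment_index(x, n, k, m)
    expect_lte(ei, 1)
    if (x > 0) expect_equal(ei, 1 - (k * n) / (m * x))    # identity
  }
  expect_error(enrichment_index(5, 4, 10, 100), "invalid")
})

test_that("hypergeometric tails: exact value, trivial class, enumeration oracle", {
  ## all 5 drawn genes in a class of 5 among 10: C(5,5)C(5,0)/C(10,5)
  expect_equal(hypergeometric_enrichment(5, 5, 5, 10), 1 / 252)
  ## the class is everything
  expect_equal(hypergeometric_enrichment(7, 7, 10, 10), 1)
  ## brute-force enumeration of all draws for small M
  brute_tail <- function(x, n, k, m, upper) {
    combs <- utils::combn(m, n)
    inclass <- colSums(combs <= k)          # items 1..k form the class
    if (upper) mean(inclass >= x) else mean(inclass <= x)
  }
  set.seed(7)
  for (i in 1:30) {
    m <- sample(6:12, 1); k <- sample(1:(m - 1), 1); n <- sample(1:(m - 1), 1)
    x <- sample(max(0, n + k - m):min(n, k), 1)
    upper <- if (x == 0) FALSE else enrichment_index(x, n, k, m) >= 0
    expect_equal(hypergeometric_enrichment(x, n, k, m),
                 brute_tail(x, n, k, m, upper),
                 tolerance = 1e-12,
                 label = sprintf("x=%d n=%d k=%d m=%d", x, n, k, m))
  }
  ## tail and complement sum to one
  for (i in 1:20) {
    m <- sample(20:100, 1); k <- sample(1:m, 1); n <- sample(1:m, 1)
    x <- sample(max(0, n + k - m):min(n, k), 1)
    up <- phyper(x - 1, k, m - k, n, lower.tail = FALSE)
    lo <- phyper(x - 1, k, m - k, n)
    expect_equal(up + lo, 1)
  }
})

test_that("BH adjustment: worked values and quadratic-time reference", {
  expect_equal(bh_fdr(0.01)$adjusted, 0.01)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03))$adjusted, c(0.03, 0.03, 0.03))
  bh_ref <- function(p) {              # textbook step-up, O(n^2)
    n <- length(p)
    o <- order(p)
    adj <- numeric(n)
    for (i in seq_len(n)) {
      vals <- vapply(i:n, function(j) n * p[o[j]] / j, numeric(1))
      adj[o[i]] <- min(1, min(vals))
    }
    adj
  }
  set.seed(8)
  for (i in 1:25) {
    p <- runif(sample(3:40, 1))
    r <- bh_fdr(p)
    expect_equal(r$adjusted, bh_ref(p))
    expect_true(all(r$adjusted >= p))
    expect_identical(r$reject, r$adjusted <= 0.05)
  }
})

test_that("functional enrichment resampling separates class-pure operons from shuffled labels", {
  set.seed(9)
  ## build a map whose operons are class-pure
  ids <- sprintf("g%03d", 1:60)
  ops <- split(ids, rep(1:20, each = 3))
  names(ops) <- NULL
  map <- structure(list(genome_id = "toy", operons = ops,
                        gene_types = setNames(rep("CDS", 60), ids),
                        pair_scores = data.frame(), circular = TRUE),
                   class = "operon_map")
  classes <- setNames(rep(sprintf("class%02d", 1:20), each = 3), ids)
  r <- functional_enrichment_resampling(map, classes, n_samples = 2000L,
                                        seed = 10L)
  expect_equal(mean(r$observed), 1)          # pure operons score 1
  expect_lt(r$p, 0.01)
  expect_gt(r$z, 0)
  ## uniformly random classes: no systematic signal. The resample count is
  ## kept comparable to the number of distinct operons, otherwise resampling
  ## a small operon pool pseudo-replicates tiny multiset differences into
  ## large rank-sum z even under the null.
  ids2 <- sprintf("h%03d", 1:300)
  ops2 <- split(ids2, rep(1:100, each = 3))
  names(ops2) <- NULL
  map2 <- structure(list(genome_id = "toy2", operons = ops2,
                         gene_types = setNames(rep("CDS", 300), ids2),
                         pair_scores = data.frame(), circular = TRUE),
                    class = "operon_map")
  zs <- vapply(1:10, function(s) {
    cls <- setNames(sample(sprintf("class%02d", 1:10), 300, TRUE), ids2)
    functional_enrichment_resampling(map2, cls, n_samples = 100L,
                                     seed = s)$z
  }, numeric(1))
  expect_lt(median(abs(zs)), 3)
  expect_gt(mean(abs(zs) < 2), 0.5)
  ## shuffling preserves class counts exactly (permutation invariant)
  set.seed(11)
  shuf <- sample(unname(classes))
  expect_equal(sort(as.integer(table(shuf))),
               sort(as.integer(table(unname(classes)))))
})
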