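## Resampling statistics: permutation test on group means with censored
## P-values, empiric P-value, gene-class enrichment index with hypergeometric
## tails, BH-FDR, and the functional-enrichment resampling comparison.

#' Permutation test on the margin between two group means
#'
#' Pools both vectors and redistributes them `n` times into two random
#' vectors of the original sizes; the absolute difference of means of each
#' redistribution is compared to the observed absolute margin. The P-value
#' is the fraction of permuted margins strictly more extreme than the
#' observed one (no pseudo-count). When that fraction is 0 the permutation
#' count is escalated tenfold once; if it is still 0 the P-value is censored
#' and reported as a bound (`P < 1/n_final`, i.e. `10^-5` at the default
#' `10^4 -> 10^5` escalation). An observed margin of exactly 0 returns
#' `p = 1` directly: with no separation at all, no redistribution is more
#' extreme in any meaningful sense.
#'
#' @param a,b numeric vectors (each length >= 2).
#' @param n permutations (default `10^4`).
#' @param seed optional integer seed.
#' @return object of class `perm_test`: `observed_margin`, `p_value`,
#'   `n_permutations`, `censored` (logical; when TRUE, `p_value` holds the
#'   bound and `bound_string` the printable form).
#' @export
permutation_test <- function(a, b, n = 10000L, seed = NULL) {
  if (length(a) < 2L || length(b) < 2L) stop2("each group needs >= 2 values")
  if (anyNA(a) || anyNA(b)) stop2("missing values in input")
  if (!is.null(seed)) set.seed(seed)
  observed <- abs(mean(a) - mean(b))
  ## redistribute by drawing the smaller group's size from the sorted pool,
  ## so the test is exactly invariant to swapping a and b at a given seed
  pooled <- sort(c(a, b))
  ns <- min(length(a), length(b))
  ntot <- length(pooled)
  count_extreme <- function(nperm) {
    cnt <- 0L
    sum_pool <- sum(pooled)
    for (i in seq_len(nperm)) {
      ia <- sample.int(ntot, ns)
      sa <- sum(pooled[ia])
      marg <- abs(sa / ns - (sum_pool - sa) / (ntot - ns))
      if (marg > observed) cnt <- cnt + 1L
    }
    cnt
  }
  if (observed == 0) {
    return(structure(list(observed_margin = 0, p_value = 1,
                          n_permutations = as.integer(n), censored = FALSE,
                          bound_string = NA_character_),
                     class = "perm_test"))
  }
  cnt <- count_extreme(n)
  n_used <- n
  if (cnt == 0L) {                       # escalate once, tenfold
    n_used <- n * 10L
    cnt <- count_extreme(n_used)
  }
  censored <- cnt == 0L
  p <- if (censored) 1 / n_used else cnt / n_used
  structure(list(observed_margin = observed, p_value = p,
                 n_permutations = as.integer(n_used), censored = censored,
                 bound_string = if (censored)
                   sprintf("P < %g", 1 / n_used) else NA_character_),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat("Permutation test on the absolute margin between group means\n")
  cat(sprintf("  observed margin: %.4g;  permutations: %d\n",
              x$observed_margin, x$n_permutations))
  if (x$censored) cat(sprintf("  %s (censored)\n", x$bound_string))
  else cat(sprintf("  P = %.4g\n", x$p_value))
  invisible(x)
}

#' Empiric P-value for a directional comparison of two groups
#'
#' Per round, draws `sample_size` values from each group (without
#' replacement when the group is large enough, with replacement otherwise)
#' and scores 1 when the objective relation between the sample means holds.
#' The returned fraction estimates P(relation holds): values near 1 support
#' the relation, values near 0.5 indicate no difference, values near 0
#' support the opposite relation.
#'
#' @param a,b numeric vectors to sample from.
#' @param sample_size draws per group per round (default 50).
#' @param rounds number of rounds (default 1000; fewer than 100 warns about
#'   resolution).
#' @param objective `"greater"` scores rounds where mean(sample of `a`) >
#'   mean(sample of `b`); `"less"` the reverse.
#' @param seed optional integer seed.
#' @return fraction in `[0, 1]`.
#' @export
empiric_pvalue <- function(a, b, sample_size = 50L, rounds = 1000L,
                           objective = c("greater", "less"), seed = NULL) {
  objective <- match.arg(objective)
  if (rounds < 100L) warning("fewer than 100 rounds gives coarse resolution")
  if (!is.null(seed)) set.seed(seed)
  draw <- function(v) {
    if (length(v) >= sample_size) sample(v, sample_size)
    else sample(v, sample_size, replace = TRUE)
  }
  hits <- vapply(seq_len(rounds), function(i) {
    ma <- mean(draw(a)); mb <- mean(draw(b))
    if (objective == "greater") ma > mb else ma < mb
  }, logical(1))
  mean(hits)
}

#' Gene-class enrichment index
#'
#' `((X/N) - (K/M)) / (X/N)` where `X` is the number of operon genes of the
#' class, `N` the total number of operon genes, `K` the class size among all
#' genes and `M` the total number of genes. Positive values mean the class
#' is over-represented among operon genes, negative depleted; the index is
#' bounded above by 1. `X = 0` returns `-Inf` ("fully depleted").
#'
#' @param x,n,k,m integers as above (vectorised).
#' @return numeric index, `<= 1`.
#' @export
enrichment_index <- function(x, n, k, m) {
  if (any(n <= 0) || any(m <= 0)) stop2("N and M must be positive")
  if (any(x < 0) || any(x > pmin(n, k)) || any(k > m))
    stop2("invalid counts: need 0 <= X <= min(N, K) and K <= M")
  ifelse(x == 0, -Inf, ((x / n) - (k / m)) / (x / n))
}

#' Hypergeometric enrichment/depletion P-value
#'
#' Under Hypergeometric(M, K, N) - drawing the `N` operon genes from `M`
#' genes of which `K` belong to the class - returns the upper tail
#' `P(X >= x)` when the class is enriched (enrichment index >= 0) and the
#' lower tail `P(X <= x)` when depleted.
#'
#' @inheritParams enrichment_index
#' @return P-value(s) in `(0, 1]`.
#' @export
hypergeometric_enrichment <- function(x, n, k, m) {
  ei <- enrichment_index(x, n, k, m)
  upper <- ei >= 0
  ifelse(upper,
         phyper(x - 1, k, m - k, n, lower.tail = FALSE),
         phyper(x, k, m - k, n))
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Standard step-up adjustment with monotonicity enforcement.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @param alpha rejection level for the returned flags (default 0.05).
#' @return list with `adjusted` (BH-adjusted P-values) and `reject`
#'   (`adjusted <= alpha`).
#' @export
bh_fdr <- function(pvalues, alpha = 0.05) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop2("P-values must lie in [0, 1]")
  adjusted <- p.adjust(pvalues, method = "BH")
  list(adjusted = adjusted, reject = adjusted <= alpha)
}

#' Functional enrichment of operons by resampling
#'
#' Scores a randomly drawn multi-gene operon by the fraction of its internal
#' adjacent gene pairs that share a functional class, repeated `n_samples`
#' times; the same sampling is repeated on a map whose gene-class labels
#' have been shuffled once (preserving class counts). The two score
#' distributions are compared with a two-tailed rank-sum test.
#'
#' @param map an `operon_map` from [assemble_operons()].
#' @param gene_classes named character vector mapping gene_id to a class
#'   label; classes must cover at least 90% of the genome's genes.
#' @param n_samples resampling draws (default 10000).
#' @param seed optional integer seed.
#' @return list with `observed` and `shuffled` score vectors, `z` (normal
#'   approximation of the rank-sum statistic) and `p` (two-tailed).
#' @export
functional_enrichment_resampling <- function(map, gene_classes,
                                             n_samples = 10000L, seed = NULL) {
  genes <- unlist(map$operons, use.names = FALSE)
  covered <- genes[genes %in% names(gene_classes)]
  if (length(covered) / length(genes) < 0.9)
    stop2("gene classes must be assigned to at least 90% of genes")
  multi <- map$operons[vapply(map$operons, length, integer(1)) >= 2L]
  if (length(multi) == 0L) stop2("no multi-gene operons to sample")
  if (!is.null(seed)) set.seed(seed)
  score_map <- function(classes) {
    scores_per_operon <- vapply(multi, function(op) {
      cls <- unname(classes[op])
      mean(cls[-length(cls)] == cls[-1L], na.rm = TRUE)
    }, numeric(1))
    scores_per_operon[sample.int(length(multi), n_samples, replace = TRUE)]
  }
  observed <- score_map(gene_classes)
  shuffled_classes <- setNames(sample(unname(gene_classes)),
                               names(gene_classes))
  shuffled <- score_map(shuffled_classes)
  w <- suppressWarnings(stats::wilcox.test(observed, shuffled,
                                           alternative = "two.sided",
                                           exact = FALSE, correct = FALSE))
  n1 <- length(observed); n2 <- length(shuffled)
  mu <- n1 * n2 / 2
  ranks <- rank(c(observed, shuffled))
  ties <- table(ranks)
  sigma <- sqrt(n1 * n2 / 12 * ((n1 + n2 + 1) -
    sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1))))
  z <- unname((w$statistic - mu) / sigma)
  list(observed = observed, shuffled = shuffled, z = z, p = w$p.value)
}

#' Write a statistics report as TSV and JSON
#'
#' @param results data.frame with columns `test`, `statistic`, `p`, `n`,
#'   `censored`.
#' @param path output stem; writes `<path>.tsv` and `<path>.json`.
#' @return the two paths, invisibly.
#' @export
write_stats_report <- function(results, path) {
  tsv <- paste0(path, ".tsv"); js <- paste0(path, ".json")
  write.table(results, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(results, js, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(c(tsv, js))
}
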