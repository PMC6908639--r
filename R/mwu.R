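#' Exact-permutation Wilcoxon-Mann-Whitney test of medians
#'
#' Permutation test on the rank-sum statistic of group `a` (midranks for
#' ties; the rank-sum orders samples identically to the Mann-Whitney U). If
#' the number of distinct group-label assignments `choose(na + nb, na)` is at
#' most `max_exact`, the null distribution is enumerated completely and the
#' p-value is the exact proportion of assignments with a statistic at least
#' as extreme as observed (two-sided: the smaller tail is doubled and capped
#' at 1). Otherwise a seeded Monte-Carlo approximation with `n_mc` random
#' assignments and the add-one correction (k + 1)/(B + 1) is used. Being a
#' rank test, the p-value is invariant under any common strictly monotone
#' transform of both samples, and robust to outliers.
#'
#' @param a,b numeric vectors (each non-empty).
#' @param alternative `"two_sided"`, `"less"` or `"greater"` (location of `a`
#'   relative to `b`).
#' @param max_exact largest number of assignments enumerated exactly.
#' @param n_mc number of Monte-Carlo assignments when exhaustive enumeration
#'   is infeasible.
#' @param seed RNG seed for the Monte-Carlo branch (ignored by the exact
#'   branch).
#' @return Object of class `mwu_test`: list with `statistic` (rank-sum of
#'   `a`), `p_value`, `method` (`"exact"` or `"monte_carlo"`),
#'   `n_permutations` (NULL for exact), and the group sizes and medians.
#' @export
exact_mwu_test <- function(a, b, alternative = c("two_sided", "less", "greater"),
                           max_exact = 2e6, n_mc = 1e5, seed = 1L) {
  alternative <- match.arg(alternative)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b)
  if (na < 1 || nb < 1) stop("both groups must be non-empty")
  n <- na + nb
  r <- rank(c(a, b), ties.method = "average")
  W <- sum(r[seq_len(na)])
  eps <- 1e-9

  n_comb <- choose(n, na)
  # the full index matrix is only materialized when it fits comfortably
  if (n_comb <= max_exact && n_comb * na <= 2.5e7) {
    idx <- utils::combn(n, na)
    stats_perm <- colSums(matrix(r[idx], nrow = na))
    p_le <- sum(stats_perm <= W + eps) / n_comb
    p_ge <- sum(stats_perm >= W - eps) / n_comb
    method <- "exact"; n_perm <- NULL
  } else {
    set.seed(seed)
    B <- max(n_mc, 1e5)
    stat_b <- vapply(seq_len(B),
                     function(i) sum(r[sample.int(n, na)]), numeric(1))
    p_le <- (sum(stat_b <= W + eps) + 1) / (B + 1)
    p_ge <- (sum(stat_b >= W - eps) + 1) / (B + 1)
    method <- "monte_carlo"; n_perm <- B
  }
  p <- switch(alternative,
              less = p_le,
              greater = p_ge,
              two_sided = min(1, 2 * min(p_le, p_ge)))
  structure(list(statistic = W, p_value = p, method = method,
                 n_permutations = n_perm, alternative = alternative,
                 n_a = na, n_b = nb,
                 median_a = stats::median(a), median_b = stats::median(b)),
            class = "mwu_test")
}

#' @export
print.mwu_test <- function(x, ...) {
  cat(sprintf(
    "Wilcoxon-Mann-Whitney permutation test (%s%s)\n  n = %d vs %d, medians %.4g vs %.4g\n  rank-sum W = %.1f, p (%s) = %.4g\n",
    x$method,
    if (!is.null(x$n_permutations)) paste0(", B = ", x$n_permutations) else "",
    x$n_a, x$n_b, x$median_a, x$median_b, x$statistic, x$alternative,
    x$p_value))
  invisible(x)
}
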