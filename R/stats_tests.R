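#' Exact Wilcoxon rank-sum test
#'
#' Two-sided Mann-Whitney / Wilcoxon rank-sum p-value. For combined sample
#' sizes up to `exact_max` all `choose(nA+nB, nA)` rank assignments are
#' enumerated (ties handled by mid-ranks); larger samples use the normal
#' approximation with tie correction. The two-sided p is
#' `min(1, 2 * min(P(W <= w), P(W >= w)))` on the rank-sum of group A.
#'
#' @param a,b numeric vectors (non-empty).
#' @param exact_max combined size at or below which enumeration is used
#'   (default 12).
#' @return list `p`, `statistic` (rank sum of `a`), `method`.
#' @export
rank_sum_exact <- function(a, b, exact_max = 12) {
  stop_if_not(length(a) > 0 && length(b) > 0, "both groups must be non-empty")
  n_a <- length(a); n_b <- length(b); n <- n_a + n_b
  r <- rank(c(a, b))
  w <- sum(r[seq_len(n_a)])
  if (n <= exact_max) {
    sets <- utils::combn(n, n_a)
    ws <- colSums(matrix(r[sets], nrow = n_a))
    p <- min(1, 2 * min(mean(ws <= w + 1e-9), mean(ws >= w - 1e-9)))
    method <- "exact"
  } else {
    mu <- n_a * (n + 1) / 2
    ties <- table(r)
    sigma2 <- n_a * n_b / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (w - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal"
  }
  list(p = p, statistic = w, method = method)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Hypergeometric tail summation: with margins fixed, the two-sided p-value
#' sums the probabilities of all tables as or less probable than the
#' observed one.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return two-sided p-value.
#' @export
fisher_exact_p <- function(table) {
  stop_if_not(all(dim(table) == c(2, 2)), "need a 2x2 table")
  stop_if_not(all(table >= 0), "negative cell count")
  m <- sum(table[1, ]); n <- sum(table[2, ]); k <- sum(table[, 1])
  x <- table[1, 1]
  support <- max(0, k - n):min(k, m)
  d <- stats::dhyper(support, m, n, k)
  sum(d[d <= stats::dhyper(x, m, n, k) * (1 + 1e-7)])
}

#' Holm-Bonferroni adjustment
#'
#' Step-down adjustment: sort ascending, multiply p_(i) by (m - i + 1),
#' enforce monotonicity, cap at 1.
#'
#' @param p raw p-values.
#' @return adjusted p-values in the input order.
#' @export
holm_adjust <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, cummax(p[o] * (m - seq_len(m) + 1)))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Fisher's exact tests with Holm-Bonferroni correction
#'
#' @param tables a single 2x2 matrix or a list of them (the m hypotheses).
#' @return data.frame `p`, `p_holm`.
#' @export
fisher_exact_with_holm <- function(tables) {
  if (is.matrix(tables)) tables <- list(tables)
  p <- vapply(tables, fisher_exact_p, numeric(1))
  data.frame(p = p, p_holm = holm_adjust(p))
}

#' Enrichment of a gene set in another, by Fisher's exact test
#'
#' Builds the 2x2 overlap table of `set_a` and `set_b` within `universe`.
#'
#' @param set_a,set_b character vectors of gene ids.
#' @param universe background gene ids.
#' @return list `table` (2x2), `p`.
#' @export
gene_set_enrichment <- function(set_a, set_b, universe) {
  a <- universe %in% set_a
  b <- universe %in% set_b
  tab <- matrix(c(sum(a & b), sum(a & !b), sum(!a & b), sum(!a & !b)),
                2, 2)
  list(table = tab, p = fisher_exact_p(tab))
}
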