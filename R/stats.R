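## Shared statistical machinery: TMM scaling of per-timepoint count tables,
## rank tests and empirical bootstrap p-values. Standard procedures are
## delegated to their canonical implementations (edgeR, stats); this module
## only fixes the conventions the pipeline relies on.

#' TMM-normalize a per-timepoint count table
#'
#' Trimmed-mean-of-M-values scaling across the columns of an items x
#' timepoints table (each column one time point/library). Scale factors come
#' from [edgeR::calcNormFactors()] with the published defaults: 30% trim on
#' log-ratios (M), 5% trim on absolute intensity (A), precision weights, and
#' the reference column chosen as the one whose upper quartile is closest to
#' the mean upper quartile. Rows containing a zero in either compared column
#' drop out of factor estimation (not out of the output). The normalized
#' table is `counts / effective library size`, rescaled so that effective
#' sizes have geometric mean one -- a table with identical columns is
#' returned unchanged.
#'
#' @param counts Numeric matrix or data.frame, items x timepoints,
#'   non-negative.
#' @param m_trim,a_trim Trim fractions for M and A values.
#' @return A `tmm_result`: list with `normalized` (same shape as input),
#'   `factors` (geometric mean 1), `ref_column`, `lib_sizes`, `m_trim`,
#'   `a_trim`.
#' @export
tmm_normalize <- function(counts, m_trim = 0.30, a_trim = 0.05) {
  x <- as.matrix(counts)
  if (!is.numeric(x)) stop("counts must be numeric", call. = FALSE)
  if (any(x < 0)) stop("counts must be non-negative", call. = FALSE)
  lib <- colSums(x)
  if (ncol(x) >= 2 && any(lib == 0)) {
    stop("column ", which(lib == 0)[1], " is all zeros", call. = FALSE)
  }
  if (ncol(x) < 2) {
    return(structure(list(normalized = counts, factors = rep(1, ncol(x)),
                          ref_column = 1L, lib_sizes = lib,
                          m_trim = m_trim, a_trim = a_trim),
                     class = "tmm_result"))
  }
  f <- edgeR::calcNormFactors(x, method = "TMM",
                              logratioTrim = m_trim, sumTrim = a_trim)
  ## reference column, edgeR's rule: upper quartile closest to the mean
  f75 <- apply(x, 2, stats::quantile, probs = 0.75) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  eff <- lib * f
  scale <- eff / exp(mean(log(eff)))
  norm <- sweep(x, 2, scale, "/")
  out <- counts
  out[] <- norm
  structure(list(normalized = out, factors = f, ref_column = ref,
                 lib_sizes = lib, m_trim = m_trim, a_trim = a_trim),
            class = "tmm_result")
}

#' @export
print.tmm_result <- function(x, ...) {
  cat("<tmm_result> factors:",
      paste(sprintf("%.4f", x$factors), collapse = " "),
      sprintf("(ref column %d)\n", x$ref_column))
  invisible(x)
}

#' Mann-Whitney U test
#'
#' Exact p by enumeration when the pooled sample size is at most 12 and
#' there are no ties; normal approximation with tie correction (and
#' continuity correction) otherwise. The returned `U` is the statistic for
#' the first sample, so `U_a + U_b = n_a * n_b`.
#'
#' @param a,b Numeric samples (non-empty).
#' @param alternative `"two.sided"`, `"less"` (a shifted below b) or
#'   `"greater"`.
#' @param exact Force the exact (`TRUE`) or approximate (`FALSE`) path;
#'   `NULL` (default) selects automatically as described above.
#' @return list with `U`, `p`, `exact` (logical), `alternative`.
#' @export
mann_whitney_u <- function(a, b, alternative = c("two.sided", "less", "greater"),
                           exact = NULL) {
  alternative <- match.arg(alternative)
  if (length(a) == 0 || length(b) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  ties <- anyDuplicated(c(a, b)) > 0
  if (is.null(exact)) {
    exact <- (length(a) + length(b) <= 12) && !ties
  } else if (exact && ties) {
    stop("exact path unavailable with ties", call. = FALSE)
  }
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = alternative,
                                            exact = exact, correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value, exact = exact,
       alternative = alternative)
}

#' Upper tail of the hypergeometric distribution
#'
#' `P(X >= k)` for `X` the number of successes in `n` draws without
#' replacement from a population of `N` containing `K` successes. Used for
#' the probability of observing at least `k` loops on a CRE.
#'
#' @param N Population size.
#' @param K Successes in the population.
#' @param n Draws.
#' @param k Observed successes.
#' @return The exact tail probability.
#' @export
hypergeometric_tail <- function(N, K, n, k) {
  if (any(c(N, K, n, k) < 0) || K > N || n > N || k > min(K, n)) {
    stop("inconsistent hypergeometric parameters", call. = FALSE)
  }
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Spearman rank correlation
#'
#' Average ranks for ties; p-value from the t approximation (the convention
#' used for all correlations reported by the pipeline).
#'
#' @param x,y Equal-length numeric vectors, length >= 3.
#' @return list with `rho`, `p`, `n`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    stop("rho undefined for a constant input vector", call. = FALSE)
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Empirical p-value from null draws
#'
#' Add-one rule, so the returned p is never zero:
#' `p_greater = (1 + #\{null >= observed\}) / (1 + #draws)`; the two-sided p
#' is twice the smaller tail, capped at 1.
#'
#' @param observed Observed statistic (scalar).
#' @param null Numeric vector of null draws (>= 100).
#' @param alternative `"greater"`, `"less"` or `"two.sided"`.
#' @return The p-value.
#' @export
empirical_p <- function(observed, null,
                        alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  if (length(null) < 100) stop("need >= 100 null draws", call. = FALSE)
  g <- (1 + sum(null >= observed)) / (1 + length(null))
  l <- (1 + sum(null <= observed)) / (1 + length(null))
  switch(alternative,
         greater = g,
         less = l,
         two.sided = min(1, 2 * min(g, l)))
}
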