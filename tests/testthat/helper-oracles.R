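## Independent oracles and small fixture builders shared across tests.

## Brute-force Gini: literal double loop over all ordered pairs.
gini_brute_force <- function(x) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) s <- s + abs(x[i] - x[j])
  }
  s / (2 * n^2 * mean(x))
}

## Direct-definition TMM factors: weighted trimmed mean of M-values against
## the reference column whose upper quartile is closest to the mean upper
## quartile; rows with a zero in either compared column are excluded;
## 30% trim on M, 5% trim on A; precision weights; factors rescaled to
## geometric mean 1. Written from the method's definition, independently of
## the package implementation.
tmm_factors_direct <- function(x, m_trim = 0.3, a_trim = 0.05) {
  x <- as.matrix(x)
  lib <- colSums(x)
  f75 <- apply(x, 2, stats::quantile, probs = 0.75) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(x)), function(j) {
    obs <- x[, j]; rc <- x[, ref]
    nO <- lib[j]; nR <- lib[ref]
    M <- log2((obs / nO) / (rc / nR))
    A <- (log2(obs / nO) + log2(rc / nR)) / 2
    v <- (nO - obs) / nO / obs + (nR - rc) / nR / rc
    fin <- is.finite(M) & is.finite(A) & A > -1e10
    M <- M[fin]; A <- A[fin]; v <- v[fin]
    if (max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    loM <- floor(n * m_trim) + 1; hiM <- n + 1 - loM
    loA <- floor(n * a_trim) + 1; hiA <- n + 1 - loA
    keep <- rank(M) >= loM & rank(M) <= hiM &
      rank(A) >= loA & rank(A) <= hiA
    2^(sum(M[keep] / v[keep]) / sum(1 / v[keep]))
  }, numeric(1))
  f / exp(mean(log(f)))
}

## A tiny CRE table at given summits (one chromosome unless given).
make_cres <- function(summits, chrom = "chr1", W = 2500,
                      cre_class = "enhancer", ar_bound = FALSE,
                      gene = NA_character_) {
  n <- length(summits)
  data.frame(cre_id = sprintf("%s:%d-%d", chrom, summits - W, summits + W),
             chrom = rep_len(chrom, n), start = summits - W,
             end = summits + W, summit = summits,
             cre_class = rep_len(cre_class, n),
             ar_bound = rep_len(ar_bound, n),
             foxa1_bound = FALSE, gene = rep_len(gene, n),
             stringsAsFactors = FALSE)
}

## A loop_set connecting CREs by row index pairs with given per-timepoint CF
## rows (matrix npairs x 5).
make_loop_set <- function(cres, pairs, cf, mark = "H3K27ac",
                          timepoints = default_timepoints()) {
  i <- pairs[, 1]; j <- pairs[, 2]
  df <- data.frame(chrom1 = cres$chrom[i], start1 = cres$start[i],
                   end1 = cres$end[i], chrom2 = cres$chrom[j],
                   start2 = cres$start[j], end2 = cres$end[j],
                   name = sprintf("l%d", seq_along(i)), mark = mark,
                   stringsAsFactors = FALSE)
  cf <- matrix(cf, nrow = length(i), ncol = length(timepoints))
  colnames(cf) <- paste0("cf_", timepoints)
  df <- cbind(df, as.data.frame(cf))
  structure(list(loops = df, mark = mark, timepoints = timepoints,
                 skip = list(inter_chromosomal = 0L, out_of_range = 0L),
                 n_input = nrow(df)),
            class = "loop_set")
}

## Small simulated dataset configuration used by pipeline-level tests.
small_sim_config <- function(seed = 11, ...) {
  sim_config(seed = seed, n_genes = 300, genes_per_chrom = 100, ...)
}
small_bootstrap <- function() bootstrap_config(iterations = 200,
                                               n_promoters = 50, seed = 7)
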