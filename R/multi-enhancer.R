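## Multi-enhancer summarization models: average / maximum / sum of a
## promoter's first-degree contact frequencies, evaluated against expression
## by expression-sorted binning, rank correlation, and ensemble-regression
## permutation importance.

#' Summarize first-degree contact frequencies per gene
#'
#' For every gene with an assigned promoter, the average, maximum and sum of
#' its promoter's first-degree edge weights at one time point. Genes whose
#' promoter has no first-degree CRE are excluded and counted.
#'
#' @param network A `loop_network`.
#' @param promoter_map data.frame `gene`, `cre_id` (from
#'   [assign_promoters()]).
#' @param mark Loop mark.
#' @param timepoint Time-point label.
#' @return data.frame `gene`, `n_contacts`, `avg`, `max`, `sum`; the number
#'   of excluded genes is attached as attribute `n_excluded`.
#' @export
summarize_models <- function(network, promoter_map, mark = "H3K27ac",
                             timepoint = "16h") {
  e <- network$edges[network$edges$mark == mark, , drop = FALSE]
  w <- e[[paste0("cf_", timepoint)]]
  map <- promoter_map[!duplicated(promoter_map$gene), c("gene", "cre_id")]
  ## expand: each edge contributes to both endpoint promoters' genes
  idx <- promoter_loop_index(e, unique(map$cre_id))
  pos <- match(map$cre_id, names(idx))
  res <- lapply(pos, function(i) {
    rows <- idx[[i]]
    if (!length(rows)) return(c(0, NA, NA, NA))
    v <- w[rows]
    c(length(v), mean(v), max(v), sum(v))
  })
  m <- do.call(rbind, res)
  out <- data.frame(gene = map$gene, n_contacts = as.integer(m[, 1]),
                    avg = m[, 2], max = m[, 3], sum = m[, 4],
                    stringsAsFactors = FALSE)
  excluded <- sum(out$n_contacts == 0)
  out <- out[out$n_contacts > 0, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- excluded
  out
}

#' Bin genes by expression and correlate against a summarized model
#'
#' Genes are sorted by expression at the time point and split into k
#' contiguous bins of equal size (any remainder spread over the first bins);
#' each bin contributes its mean `log(expression + eps)` and mean summarized
#' contact frequency. The reported correlation is Spearman's rho over the k
#' bin means (a gene-level rho is reported alongside).
#'
#' @param summaries Output of [summarize_models()].
#' @param expression Gene-level expression table (`gene`, `tpm_<label>`).
#' @param model `"avg"`, `"max"` or `"sum"`.
#' @param timepoint Time-point label.
#' @param k Number of bins (default 25).
#' @param eps Expression pseudocount for the log axis.
#' @return A `model_fit`: `model`, `mark`-free bin table (`bins`), `rho`,
#'   `p`, `rho_gene`, `p_gene`, `n_genes`, `k`.
#' @export
bin_and_correlate <- function(summaries, expression, model = c("sum", "max", "avg"),
                              timepoint = "16h", k = 25, eps = 0.01) {
  model <- match.arg(model)
  tcol <- paste0("tpm_", timepoint)
  df <- merge(summaries, expression[c("gene", tcol)], by = "gene")
  n <- nrow(df)
  if (n < k) stop("need at least k = ", k, " genes, got ", n, call. = FALSE)
  df <- df[order(df[[tcol]], df$gene), ]
  sizes <- rep(n %/% k, k)
  if (n %% k > 0) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1L
  bin <- rep(seq_len(k), times = sizes)
  log_expr <- log(df[[tcol]] + eps)
  bins <- data.frame(
    bin = seq_len(k),
    n = sizes,
    mean_log_expr = as.numeric(tapply(log_expr, bin, mean)),
    mean_cf = as.numeric(tapply(df[[model]], bin, mean)))
  ct <- spearman_cor(bins$mean_log_expr, bins$mean_cf)
  ctg <- spearman_cor(log_expr, df[[model]])
  structure(list(model = model, timepoint = timepoint, k = k, bins = bins,
                 rho = ct$rho, p = ct$p, rho_gene = ctg$rho, p_gene = ctg$p,
                 n_genes = n),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("<model_fit> %s @ %s: bin-level rho=%.3f (p=%.3g), gene-level rho=%.3f, n=%d, k=%d\n",
              x$model, x$timepoint, x$rho, x$p, x$rho_gene, x$n_genes, x$k))
  invisible(x)
}

#' Random-forest feature importance of the three summarization models
#'
#' Trains a random forest regressor on the binned `avg` / `max` / `sum`
#' features to predict binned expression, with every feature considered at
#' each split, and ranks features by permutation importance: the mean
#' decrease in training R^2 over seeded shuffles of one feature at a time.
#'
#' @param features data.frame (or matrix) of binned features with columns
#'   `avg`, `max`, `sum` (>= 25 rows).
#' @param target Numeric binned expression, same length.
#' @param seed RNG seed controlling forest construction and shuffles.
#' @param n_shuffles Shuffles per feature (default 10).
#' @param ntree Trees in the forest.
#' @return list with `r2` (training R^2), `importance` (named, sorted
#'   decreasing), `ranking` (feature names, best first), `fit`.
#' @export
feature_importance <- function(features, target, seed = 0, n_shuffles = 10,
                               ntree = 500) {
  features <- as.data.frame(features)[c("avg", "max", "sum")]
  if (nrow(features) < 25) {
    stop("need >= 25 binned observations", call. = FALSE)
  }
  if (length(target) != nrow(features)) {
    stop("target length must match features", call. = FALSE)
  }
  if (length(unique(target)) < 2) {
    stop("constant target: nothing to regress", call. = FALSE)
  }
  d <- cbind(features, .y = target)
  r2 <- function(pred) 1 - sum((pred - target)^2) / sum((target - mean(target))^2)
  with_rng(seed, {
    fit <- randomForest::randomForest(.y ~ avg + max + sum, data = d,
                                      ntree = ntree, mtry = 3)
    base <- r2(stats::predict(fit, d))
    imp <- vapply(c("avg", "max", "sum"), function(f) {
      mean(vapply(seq_len(n_shuffles), function(i) {
        dp <- d
        dp[[f]] <- sample(dp[[f]])
        base - r2(stats::predict(fit, dp))
      }, numeric(1)))
    }, numeric(1))
    imp <- sort(imp, decreasing = TRUE)
    list(r2 = base, importance = imp, ranking = names(imp), fit = fit)
  })
}
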