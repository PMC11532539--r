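## Bootstrapped contact-frequency fold changes from promoter and enhancer
## viewpoints, temporal SD dynamics, and correlation of loop dynamics with
## perturbation effect sizes.

#' Bootstrap configuration for fold-change estimation
#'
#' @param iterations Number of bootstrap iterations b (>= 100).
#' @param n_promoters Promoters drawn per iteration (fixed n).
#' @param seed RNG seed of the bootstrap stream.
#' @return A `bootstrap_config` list.
#' @export
bootstrap_config <- function(iterations = 1000, n_promoters = 100, seed = 7) {
  if (iterations < 100) stop("iterations must be >= 100", call. = FALSE)
  if (n_promoters < 1) stop("n_promoters must be >= 1", call. = FALSE)
  structure(list(iterations = as.integer(iterations),
                 n_promoters = as.integer(n_promoters),
                 seed = as.integer(seed)),
            class = "bootstrap_config")
}

## Per-stratum target counts matching the query's composition, scaled to n.
strata_targets <- function(query, strata, n) {
  if (is.null(strata)) return(NULL)
  comp <- table(strata[query])
  tgt <- round(as.numeric(comp) / sum(comp) * n)
  ## fix rounding so the targets sum to n
  d <- n - sum(tgt)
  if (d != 0) tgt[which.max(tgt)] <- tgt[which.max(tgt)] + d
  stats::setNames(tgt, names(comp))
}

## Core bootstrap: loop_rows maps promoter id -> integer rows of cf matrix.
## Per-promoter loop-CF sums are precomputed, so the mean contact frequency
## of a drawn promoter set is two indexed reductions per iteration (a loop
## anchored at two drawn promoters contributes once per viewpoint).
## Observed FC uses the (possibly per-iteration subsampled) query; the
## matched null replaces the query by an independent reference-style draw.
boot_fc_engine <- function(cf, loop_rows, query, pool, config,
                           timepoints, strata = NULL) {
  b <- config$iterations
  n <- config$n_promoters
  if (length(pool) < n) {
    stop("reference pool smaller than n_promoters", call. = FALSE)
  }
  prom_ids <- names(loop_rows)
  S <- t(vapply(loop_rows,
                function(r) colSums(cf[r, , drop = FALSE]),
                numeric(ncol(cf))))
  C <- lengths(loop_rows)
  q_idx <- match(query, prom_ids)
  pool_idx <- match(pool, prom_ids)
  targets <- strata_targets(query, strata, n)
  pool_split <- if (!is.null(strata)) {
    split(pool_idx, as.character(strata[pool]))
  } else NULL
  draw_ref <- function() {
    if (is.null(pool_split)) return(pool_idx[sample.int(length(pool_idx), n)])
    picked <- unlist(lapply(names(targets), function(s) {
      cand <- pool_split[[s]]
      if (is.null(cand)) return(integer(0))
      m <- min(targets[[s]], length(cand))
      cand[sample.int(length(cand), m)]
    }), use.names = FALSE)
    short <- n - length(picked)
    if (short > 0) {
      rest <- setdiff(pool_idx, picked)
      picked <- c(picked, rest[sample.int(length(rest), min(short, length(rest)))])
    }
    picked
  }
  mean_set <- function(idx) {
    cnt <- sum(C[idx])
    if (cnt == 0) return(rep(NA_real_, ncol(cf)))
    colSums(S[idx, , drop = FALSE]) / cnt
  }
  subsample_query <- length(q_idx) > n
  q_fixed <- if (!subsample_query) mean_set(q_idx) else NULL
  fc <- matrix(NA_real_, b, ncol(cf))
  null_fc <- matrix(NA_real_, b, ncol(cf))
  discarded <- 0L
  with_rng(config$seed, {
    for (i in seq_len(b)) {
      ref_mean <- mean_set(draw_ref())
      if (any(is.na(ref_mean)) || any(ref_mean == 0)) {
        discarded <- discarded + 1L
        next
      }
      qm <- if (subsample_query) {
        mean_set(q_idx[sample.int(length(q_idx), n)])
      } else q_fixed
      fc[i, ] <- qm / ref_mean
      null_fc[i, ] <- mean_set(draw_ref()) / ref_mean
    }
  })
  ok <- !is.na(fc[, 1])
  if (discarded > 0.05 * b) {
    warning(sprintf("%d of %d iterations discarded (zero reference mean)",
                    discarded, b), call. = FALSE)
  }
  fc <- fc[ok, , drop = FALSE]
  null_fc <- null_fc[ok, , drop = FALSE]
  mean_fc <- colMeans(fc)
  ci <- apply(fc, 2, stats::quantile, probs = c(0.025, 0.975))
  p_two <- vapply(seq_along(timepoints), function(j) {
    empirical_p(mean_fc[j], null_fc[, j], alternative = "two.sided")
  }, numeric(1))
  peak <- which.max(mean_fc)
  p_peak <- empirical_p(mean_fc[peak], null_fc[, peak],
                        alternative = "greater")
  structure(list(
    summary = data.frame(timepoint = timepoints, mean_fc = mean_fc,
                         ci_lo = ci[1, ], ci_hi = ci[2, ], p_two = p_two,
                         stringsAsFactors = FALSE),
    peak_timepoint = timepoints[peak], p_peak = p_peak,
    discarded = discarded, iterations_used = sum(ok), config = config),
    class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap_result> b=%d n=%d seed=%d; peak %s (p=%.4g)\n",
              x$config$iterations, x$config$n_promoters, x$config$seed,
              x$peak_timepoint, x$p_peak))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

## promoter id -> integer rows of the mark's edge table (both endpoints)
promoter_loop_index <- function(edges, promoter_ids) {
  idx1 <- split(which(edges$node1 %in% promoter_ids),
                edges$node1[edges$node1 %in% promoter_ids])
  idx2 <- split(which(edges$node2 %in% promoter_ids),
                edges$node2[edges$node2 %in% promoter_ids])
  out <- stats::setNames(vector("list", length(promoter_ids)), promoter_ids)
  for (p in names(idx1)) out[[p]] <- idx1[[p]]
  for (p in names(idx2)) out[[p]] <- c(out[[p]], idx2[[p]])
  out
}

#' Bootstrapped contact-frequency fold change, promoter viewpoint
#'
#' Per iteration, `n` reference promoters are drawn without replacement from
#' the reference pool (optionally stratified to match the query's expression
#' quartile composition) and the fold change at each time point is the mean
#' contact frequency of the query promoters' loops over the mean of that
#' iteration's reference loops -- each time point against its own reference,
#' so a flat profile near 1 indicates matched baselines. Significance comes
#' from a matched null in which the query is itself a size-n reference draw:
#' per-timepoint two-sided empirical p, and a one-sided (greater) p at the
#' time point of maximal mean fold change.
#'
#' @param network A `loop_network`.
#' @param query_promoters CRE ids of the query promoters (each with >= 1
#'   loop).
#' @param reference_pool CRE ids of reference promoters (>= n).
#' @param mark Loop mark.
#' @param config A [bootstrap_config()].
#' @param strata Optional named character vector (promoter CRE id ->
#'   stratum, e.g. expression quartile) used to match reference draws to the
#'   query composition.
#' @return A `bootstrap_result`.
#' @export
bootstrap_fc_promoter_view <- function(network, query_promoters,
                                       reference_pool, mark = "H3K27ac",
                                       config = bootstrap_config(),
                                       strata = NULL) {
  e <- network$edges[network$edges$mark == mark, , drop = FALSE]
  cf <- as.matrix(e[cf_cols(network$timepoints)])
  all_p <- union(query_promoters, reference_pool)
  loop_rows <- promoter_loop_index(e, all_p)
  if (!length(unlist(loop_rows[query_promoters]))) {
    stop("query promoters have no loops for mark ", mark, call. = FALSE)
  }
  boot_fc_engine(cf, loop_rows, query_promoters, reference_pool, config,
                 network$timepoints, strata)
}

#' Bootstrapped contact-frequency fold change, enhancer viewpoint
#'
#' Loop sets are restricted to enhancer-promoter edges matching a selector:
#' `"E+AR->P+AR"` (AR-bound enhancers looped to regulated-gene promoters),
#' `"E-AR->P+AR"` (AR-free enhancers looped to the same promoters) or
#' `"E-AR->P-AR"` (AR-free enhancers looped to highly expressed independent
#' promoters). The reference is always the loops of AR-free enhancers to
#' independent highly expressed promoters, with `n` promoters drawn per
#' iteration on both sides (the query promoters are subsampled to `n` per
#' iteration when there are more).
#'
#' @param network A `loop_network`.
#' @param cres CRE table with classes and `ar_bound` flags.
#' @param selector One of the three loop-set selectors above.
#' @param query_promoters Regulated-gene promoter CRE ids (used by the
#'   `P+AR` selectors).
#' @param reference_promoters Highly expressed independent-gene promoter CRE
#'   ids (reference pool, and query pool for `"E-AR->P-AR"`).
#' @param mark Loop mark.
#' @param config A [bootstrap_config()].
#' @param strata Optional promoter stratification (see
#'   [bootstrap_fc_promoter_view()]).
#' @return A `bootstrap_result`.
#' @export
bootstrap_fc_enhancer_view <- function(network, cres,
                                       selector = c("E+AR->P+AR",
                                                    "E-AR->P+AR",
                                                    "E-AR->P-AR"),
                                       query_promoters, reference_promoters,
                                       mark = "H3K27ac",
                                       config = bootstrap_config(),
                                       strata = NULL) {
  selector <- match.arg(selector)
  tpcols <- cf_cols(network$timepoints)
  e <- network$edges[network$edges$mark == mark, , drop = FALSE]
  cls <- cres$cre_class[match(e$node1, cres$cre_id)]
  cls2 <- cres$cre_class[match(e$node2, cres$cre_id)]
  ar1 <- cres$ar_bound[match(e$node1, cres$cre_id)]
  ar2 <- cres$ar_bound[match(e$node2, cres$cre_id)]
  ep <- (cls == "promoter" & cls2 == "enhancer") |
    (cls == "enhancer" & cls2 == "promoter")
  prom_node <- ifelse(cls == "promoter", e$node1, e$node2)
  enh_ar <- ifelse(cls == "promoter", ar2, ar1)

  query_ar <- startsWith(selector, "E+AR")
  query_pool <- if (endsWith(selector, "P+AR")) query_promoters else
    reference_promoters
  q_sel <- ep & enh_ar == query_ar & prom_node %in% query_pool
  if (!any(q_sel)) {
    stop("selector ", selector, " matches zero loops", call. = FALSE)
  }
  r_sel <- ep & !enh_ar & prom_node %in% reference_promoters
  if (!any(r_sel)) {
    stop("reference selector E-AR->P-AR matches zero loops", call. = FALSE)
  }
  ## index loops by their promoter endpoint within each selection
  rows_by_prom <- function(sel) split(which(sel), prom_node[sel])
  q_rows <- rows_by_prom(q_sel)
  r_rows <- rows_by_prom(r_sel)
  ## merge into one promoter->rows map with distinct promoter namespaces
  loop_rows <- c(stats::setNames(q_rows, paste0("q:", names(q_rows))),
                 stats::setNames(r_rows, paste0("r:", names(r_rows))))
  cf <- as.matrix(e[tpcols])
  query_ids <- paste0("q:", names(q_rows))
  pool_ids <- paste0("r:", names(r_rows))
  strata2 <- NULL
  if (!is.null(strata)) {
    strata2 <- c(stats::setNames(strata[names(q_rows)], query_ids),
                 stats::setNames(strata[names(r_rows)], pool_ids))
  }
  boot_fc_engine(cf, loop_rows, query_ids, pool_ids, config,
                 network$timepoints, strata2)
}

#' Temporal standard deviation, min-max normalized within groups
#'
#' Sample SD (n - 1) of each item's feature across the time course, then
#' min-max normalization within each comparison group (e.g. per gene across
#' its enhancers). A single-item group gets normalized value 1 (logged).
#'
#' @param mat Items x timepoints numeric matrix (all time points present).
#' @param groups Optional grouping vector (length nrow); default one group.
#' @param items Optional item ids (default rownames).
#' @return data.frame `item`, `group`, `sd`, `sd_scaled` (in `[0, 1]`).
#' @export
temporal_sd_profile <- function(mat, groups = NULL, items = NULL) {
  mat <- as.matrix(mat)
  if (is.null(items)) items <- rownames(mat)
  if (is.null(items)) items <- as.character(seq_len(nrow(mat)))
  if (is.null(groups)) groups <- rep("all", nrow(mat))
  sds <- apply(mat, 1, stats::sd)
  mn <- stats::ave(sds, groups, FUN = min)
  mx <- stats::ave(sds, groups, FUN = max)
  size <- stats::ave(sds, groups, FUN = length)
  scaled <- ifelse(size == 1 | mx == mn, 1, (sds - mn) / (mx - mn))
  if (any(size == 1)) {
    message(sum(size == 1), " single-item group(s): normalized SD set to 1")
  }
  data.frame(item = items, group = groups, sd = sds, sd_scaled = scaled,
             stringsAsFactors = FALSE)
}

#' Correlate perturbation effect sizes with loop dynamics
#'
#' Spearman correlation between per-CRE perturbation effects (e.g. CRISPRi
#' knockdown of stimulated expression) and the temporal SD of the CRE's
#' contact frequency. The sign is reported, not assumed.
#'
#' @param dynamics data.frame with `cre_id` (or `item`) and `sd` columns.
#' @param effects data.frame with `cre_id` and `effect` columns.
#' @return list with `rho`, `p`, `n` (shared CREs).
#' @export
correlate_perturbation <- function(dynamics, effects) {
  idcol <- if ("cre_id" %in% names(dynamics)) "cre_id" else "item"
  shared <- intersect(dynamics[[idcol]], effects$cre_id)
  if (length(shared) < 3) {
    stop("need >= 3 shared CREs between dynamics and effects", call. = FALSE)
  }
  x <- dynamics$sd[match(shared, dynamics[[idcol]])]
  y <- effects$effect[match(shared, effects$cre_id)]
  c(spearman_cor(x, y), list(n = length(shared)))
}
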