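## Dominant-loop calling: per-promoter min-max scaling of first-degree
## contact frequencies, a >0.8 threshold, and the Gini inequality index of
## the promoter's contact distribution.

#' Gini inequality index
#'
#' Relative mean absolute difference over all ordered pairs:
#' `G = sum_i sum_j |x_i - x_j| / (2 n^2 mean(x))`. Zero for perfect equality
#' (including a single item), approaching 1 as one item takes everything;
#' scale-invariant.
#'
#' @param x Non-negative numeric vector, not all zero.
#' @return G in `[0, 1)`.
#' @export
gini_index <- function(x) {
  if (length(x) < 1) stop("x must be non-empty", call. = FALSE)
  if (any(x < 0)) stop("negative value in x", call. = FALSE)
  if (all(x == 0)) stop("Gini undefined for an all-zero vector", call. = FALSE)
  n <- length(x)
  ## sum of |xi - xj| over ordered pairs via the sorted-vector identity
  s <- sort(x)
  mad_sum <- 2 * sum((2 * seq_len(n) - n - 1) * s)
  mad_sum / (2 * n^2 * mean(x))
}

## Shared engine: per-promoter min-max scaling of a loops x timepoints CF
## matrix, threshold call per timepoint, "any" aggregate. Also used by the
## synthetic generator to plant truth with the exact calling rule.
## Returns scaled (matrix, NA where the neighborhood is degenerate at that
## timepoint), dominant (logical matrix), dominant_any, balanced_any.
dominance_flags <- function(promoter, cf, threshold = 0.8) {
  stopifnot(is.matrix(cf), length(promoter) == nrow(cf))
  g <- match(promoter, unique(promoter))
  size <- tabulate(g)
  dt <- data.table::as.data.table(cf)
  dt$..g <- g
  ## grouped scans; data.table's `by` preserves first-appearance order, so
  ## group row i corresponds to group index i
  mins <- as.matrix(dt[, lapply(.SD, min), by = "..g"][, -1])
  maxs <- as.matrix(dt[, lapply(.SD, max), by = "..g"][, -1])
  scaled <- cf
  dominant <- matrix(FALSE, nrow(cf), ncol(cf))
  balanced <- matrix(FALSE, nrow(cf), ncol(cf))
  single <- size[g] == 1
  for (j in seq_len(ncol(cf))) {
    mn <- mins[g, j]
    rng <- maxs[g, j] - mn
    flat <- rng == 0 & !single
    s <- (cf[, j] - mn) / rng
    s[single] <- 1
    s[flat] <- NA
    scaled[, j] <- s
    dominant[, j] <- !is.na(s) & s > threshold
    balanced[, j] <- flat
  }
  list(scaled = scaled, dominant = dominant,
       dominant_any = rowSums(dominant) > 0,
       balanced_any = rowSums(balanced) > 0,
       group = g, group_size = size[g])
}

#' Call dominant loops per promoter
#'
#' At every time point the contact frequencies of a promoter's first-degree
#' CREs are min-max scaled to `[0, 1]`; neighbors above the threshold are
#' dominant at that time point. A single-neighbor promoter's CRE is dominant
#' by convention (scaled value 1); a neighborhood with all-equal contact
#' frequencies yields no dominant call and is flagged balanced. The aggregate
#' call is "dominant at any time point" (default policy) or at one named
#' time point. The Gini index of the promoter's raw contact-frequency
#' distribution is reported at `gini_timepoint`.
#'
#' @param network A `loop_network`.
#' @param cres CRE table (classes assigned).
#' @param promoters Promoter CRE ids to score (default: all promoter-class
#'   CREs with at least one neighbor).
#' @param mark Loop mark to use.
#' @param threshold Scaled-CF threshold (default 0.8, exclusive).
#' @param policy `"any"` or one time-point label.
#' @param gini_timepoint Time point at which the Gini index is computed.
#' @return A `dominance_calls` object: `loops` (per promoter-neighbor row:
#'   scaled CFs, per-timepoint and aggregate dominant flags), `promoters`
#'   (neighborhood size, balanced flag, Gini), plus the call parameters.
#' @export
call_dominant_loops <- function(network, cres, promoters = NULL,
                                mark = "H3K27ac", threshold = 0.8,
                                policy = "any", gini_timepoint = "16h") {
  tp <- network$timepoints
  if (!identical(policy, "any") && !policy %in% tp) {
    stop("policy must be \"any\" or one of the time-point labels",
         call. = FALSE)
  }
  if (is.null(promoters)) {
    promoters <- cres$cre_id[cres$cre_class == "promoter"]
  }
  e <- network$edges[network$edges$mark == mark, , drop = FALSE]
  in1 <- e$node1 %in% promoters
  in2 <- e$node2 %in% promoters
  ## each edge contributes to the neighborhood of each promoter endpoint
  loops <- rbind(
    data.frame(promoter = e$node1[in1], neighbor = e$node2[in1],
               e[in1, cf_cols(tp)], stringsAsFactors = FALSE),
    data.frame(promoter = e$node2[in2], neighbor = e$node1[in2],
               e[in2, cf_cols(tp)], stringsAsFactors = FALSE))
  if (!nrow(loops)) stop("no loops found for the given promoters", call. = FALSE)
  loops <- loops[order(loops$promoter, loops$neighbor), ]
  rownames(loops) <- NULL
  cf <- as.matrix(loops[cf_cols(tp)])
  fl <- dominance_flags(loops$promoter, cf, threshold)
  colnames(fl$scaled) <- paste0("scaled_", tp)
  colnames(fl$dominant) <- paste0("dominant_", tp)
  loops <- cbind(loops, as.data.frame(fl$scaled), as.data.frame(fl$dominant))
  loops$dominant <- if (identical(policy, "any")) {
    fl$dominant_any
  } else {
    fl$dominant[, paste0("dominant_", policy)]
  }
  gcol <- cf[, paste0("cf_", gini_timepoint)]
  prom_ids <- unique(loops$promoter)
  gini <- vapply(split(gcol, fl$group), function(v) {
    if (all(v == 0)) NA_real_ else gini_index(v)
  }, numeric(1))
  bal <- tapply(fl$balanced_any, fl$group, any)
  prom_tab <- data.frame(promoter = prom_ids,
                         n_neighbors = tabulate(fl$group),
                         balanced = as.logical(
                           bal[as.character(seq_along(prom_ids))]),
                         gini = unname(gini[as.character(seq_along(prom_ids))]),
                         stringsAsFactors = FALSE)
  structure(list(loops = loops, promoters = prom_tab, mark = mark,
                 threshold = threshold, policy = policy,
                 gini_timepoint = gini_timepoint, timepoints = tp),
            class = "dominance_calls")
}

#' @export
print.dominance_calls <- function(x, ...) {
  cat(sprintf(
    "<dominance_calls> %d promoters, %d loops, %d dominant (mark %s, threshold %.2f, policy %s)\n",
    nrow(x$promoters), nrow(x$loops), sum(x$loops$dominant), x$mark,
    x$threshold, x$policy))
  cat(sprintf("  mean Gini at %s: %.3f\n", x$gini_timepoint,
              mean(x$promoters$gini, na.rm = TRUE)))
  invisible(x)
}

#' Compare contact-frequency dynamics of dominant vs non-dominant loops
#'
#' Two-sided Mann-Whitney U of the temporal standard deviation of contact
#' frequency between dominant (D+) and non-dominant (D-) loops, optionally
#' restricted (e.g. to AR-bound CREs looped to regulated promoters).
#'
#' @param calls A `dominance_calls` object.
#' @param dynamics data.frame with `promoter`, `neighbor`, `sd` (e.g. from
#'   [temporal_sd_profile()] on the same loop table).
#' @param neighbors Optional CRE ids; only loops whose neighbor is in the set
#'   are compared.
#' @param promoters Optional promoter CRE ids restriction.
#' @return list with the U test (`U`, `p`), group sizes and medians.
#' @export
compare_dominant_dynamics <- function(calls, dynamics, neighbors = NULL,
                                      promoters = NULL) {
  lo <- calls$loops
  key <- paste0(lo$promoter, "|", lo$neighbor)
  dyn_key <- paste0(dynamics$promoter, "|", dynamics$neighbor)
  sd_val <- dynamics$sd[match(key, dyn_key)]
  keep <- !is.na(sd_val)
  if (!is.null(neighbors)) keep <- keep & lo$neighbor %in% neighbors
  if (!is.null(promoters)) keep <- keep & lo$promoter %in% promoters
  dplus <- sd_val[keep & lo$dominant]
  dminus <- sd_val[keep & !lo$dominant]
  if (!length(dplus)) stop("dominant group (D+) is empty", call. = FALSE)
  if (!length(dminus)) stop("non-dominant group (D-) is empty", call. = FALSE)
  mw <- mann_whitney_u(dplus, dminus, alternative = "two.sided")
  list(U = mw$U, p = mw$p, n_dominant = length(dplus),
       n_nondominant = length(dminus),
       median_dominant = stats::median(dplus),
       median_nondominant = stats::median(dminus))
}

#' Fraction of promoters whose dominant CRE is also the closest CRE
#'
#' Distance is the genomic gap between the CRE window and the promoter
#' window (zero when they overlap). A promoter counts as "proximal-dominant"
#' when any of its dominant CREs attains the minimal distance among its
#' neighbors.
#'
#' @param calls A `dominance_calls` object.
#' @param cres CRE table (coordinates).
#' @return list with `fraction` (`NA` when there is no dominant call at
#'   all), `n_promoters`, `n_proximal`.
#' @export
dominant_proximity_fraction <- function(calls, cres) {
  lo <- calls$loops
  i <- match(lo$promoter, cres$cre_id)
  j <- match(lo$neighbor, cres$cre_id)
  gap <- pmax(cres$start[i] - cres$end[j], cres$start[j] - cres$end[i], 0)
  has_dom <- tapply(lo$dominant, lo$promoter, any)
  proms <- names(has_dom)[has_dom]
  if (!length(proms)) {
    return(list(fraction = NA_real_, n_promoters = 0L, n_proximal = 0L))
  }
  min_gap <- tapply(gap, lo$promoter, min)
  prox <- vapply(proms, function(p) {
    sel <- lo$promoter == p
    any(lo$dominant[sel] & gap[sel] == min_gap[[p]])
  }, logical(1))
  list(fraction = mean(prox), n_promoters = length(proms),
       n_proximal = sum(prox))
}
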