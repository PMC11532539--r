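## CRE annotation: fixed-width windows around accessibility summits, active
## promoter assignment from the highest-expressed isoform per gene, binding
## flags from ChIP peak overlap, and expression-derived gene sets.

## interval data.frame (0-based half-open) -> GRanges (1-based closed)
as_granges <- function(x) {
  GenomicRanges::GRanges(x$chrom,
                         IRanges::IRanges(start = x$start + 1L, end = x$end))
}

cre_granges <- function(cres) {
  GenomicRanges::GRanges(cres$chrom,
                         IRanges::IRanges(start = cres$start + 1L,
                                          end = cres$end))
}

#' Define CREs from accessibility summits
#'
#' Each summit opens a fixed window `[summit - W, summit + W)`. Summit sets
#' are processed in the order given (one element per time point); a summit
#' falling inside an already-accepted window is absorbed into it, so each
#' accessible region yields exactly one CRE however many time points it is
#' called in. Within one set, summits are resolved in coordinate order.
#'
#' @param peaks A single interval data.frame (see [read_intervals()]) or a
#'   list of them, one per time point, in time order. Every peak must carry a
#'   summit.
#' @param half_width Window half-width W in bases (default 2500, i.e. +/-2.5
#'   kb around the summit).
#' @return data.frame of CREs: `cre_id`, `chrom`, `start`, `end`, `summit`
#'   (absolute position), `cre_class` (NA until classified), `ar_bound`,
#'   `foxa1_bound`, `gene`; sorted by coordinate, ids unique.
#' @export
define_cres <- function(peaks, half_width = 2500) {
  if (is.data.frame(peaks)) peaks <- list(peaks)
  W <- as.integer(half_width)
  acc_chrom <- character(0)
  acc_summit <- integer(0)
  for (pk in peaks) {
    if (!nrow(pk)) next
    if (any(is.na(pk$summit))) {
      stop("peak without resolvable summit", call. = FALSE)
    }
    s_abs <- pk$start + pk$summit
    ## drop summits already inside an accepted window
    if (length(acc_summit)) {
      keep <- rep(TRUE, length(s_abs))
      for (ch in unique(pk$chrom)) {
        idx <- which(pk$chrom == ch)
        a <- acc_summit[acc_chrom == ch]
        if (!length(a)) next
        hit <- IRanges::overlapsAny(
          IRanges::IRanges(s_abs[idx] + 1L, s_abs[idx] + 1L),
          IRanges::IRanges(a - W + 1L, a + W))
        keep[idx] <- !hit
      }
      s_abs <- s_abs[keep]
      chs <- pk$chrom[keep]
    } else {
      chs <- pk$chrom
    }
    ## within this round: coordinate-ordered greedy scan per chromosome
    if (length(s_abs)) {
      o <- order(chs, s_abs)
      chs <- chs[o]; s_abs <- s_abs[o]
      take <- logical(length(s_abs))
      last_ch <- ""
      last_s <- -Inf
      for (i in seq_along(s_abs)) {
        if (chs[i] != last_ch || s_abs[i] >= last_s + W) {
          take[i] <- TRUE
          last_ch <- chs[i]
          last_s <- s_abs[i]
        }
      }
      acc_chrom <- c(acc_chrom, chs[take])
      acc_summit <- c(acc_summit, s_abs[take])
    }
  }
  o <- order(acc_chrom, acc_summit)
  chrom <- acc_chrom[o]; summit <- acc_summit[o]
  start <- summit - W
  end <- summit + W
  data.frame(cre_id = sprintf("%s:%d-%d", chrom, start, end),
             chrom = chrom, start = start, end = end, summit = summit,
             cre_class = NA_character_, ar_bound = FALSE, foxa1_bound = FALSE,
             gene = NA_character_, stringsAsFactors = FALSE)
}

## strand-aware TSS of a transcript interval [start, end) (0-based)
transcript_tss <- function(start, end, strand) {
  ifelse(strand == "-", end - 1L, start)
}

#' Assign active promoters from per-isoform expression
#'
#' For each gene the single highest-expressed isoform (maximum over time
#' points; ties broken toward the lexicographically smallest transcript id)
#' contributes a TSS window `[tss - W, tss + W)`. A CRE overlapping that
#' window by at least one base becomes the gene's active promoter; with
#' several overlapping CREs the one with maximal overlap wins (logged as
#' ambiguous). Genes with no overlapping CRE get no active promoter and are
#' excluded from promoter-anchored analyses.
#'
#' @param cres CRE table from [define_cres()].
#' @param transcripts data.frame with `transcript`, `gene`, `chrom`, `start`,
#'   `end`, `strand` and `tpm_<label>` columns (coordinates 0-based
#'   half-open).
#' @param timepoints Time-point labels.
#' @param half_width TSS window half-width (default 2500).
#' @return list with `cres` (promoter class + gene filled in), `map`
#'   (data.frame gene/cre_id/transcript/tss/strand), `excluded_genes`,
#'   `ambiguous_genes`.
#' @export
assign_promoters <- function(cres, transcripts,
                             timepoints = default_timepoints(),
                             half_width = 2500) {
  W <- as.integer(half_width)
  tc <- tpm_cols(timepoints)
  missing_cols <- setdiff(tc, names(transcripts))
  if (length(missing_cols)) {
    stop("transcripts table missing column ", missing_cols[1], call. = FALSE)
  }
  tx <- transcripts
  tx$max_tpm <- do.call(pmax, tx[tc])
  ## highest-expressed isoform per gene, ties -> smallest transcript id
  tx <- tx[order(tx$gene, -tx$max_tpm, tx$transcript), ]
  top <- tx[!duplicated(tx$gene), ]
  top$tss <- transcript_tss(top$start, top$end, top$strand)

  win <- GenomicRanges::GRanges(
    top$chrom, IRanges::IRanges(start = top$tss - W + 1L, end = top$tss + W))
  ov <- GenomicRanges::findOverlaps(win, cre_granges(cres))
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  ow <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(win)[qh], IRanges::ranges(cre_granges(cres))[sh]))
  ambiguous <- unique(top$gene[qh[duplicated(qh) | duplicated(qh, fromLast = TRUE)]])
  ## keep maximal overlap per gene; ties -> leftmost CRE
  o <- order(qh, -ow, cres$start[sh])
  qh <- qh[o]; sh <- sh[o]
  keep <- !duplicated(qh)
  qh <- qh[keep]; sh <- sh[keep]

  map <- data.frame(gene = top$gene[qh], cre_id = cres$cre_id[sh],
                    transcript = top$transcript[qh], tss = top$tss[qh],
                    strand = top$strand[qh], stringsAsFactors = FALSE)
  excluded <- setdiff(top$gene, map$gene)
  if (length(excluded)) {
    message(length(excluded), " gene(s) without an overlapping CRE excluded ",
            "from promoter-anchored analyses")
  }
  if (length(ambiguous)) {
    message(length(ambiguous),
            " gene(s) had TSS windows overlapping multiple CREs; ",
            "assigned by maximal overlap")
  }
  cres$cre_class[cres$cre_id %in% map$cre_id] <- "promoter"
  first_gene <- map[!duplicated(map$cre_id), ]
  cres$gene[match(first_gene$cre_id, cres$cre_id)] <- first_gene$gene
  list(cres = cres, map = map, excluded_genes = excluded,
       ambiguous_genes = ambiguous)
}

#' Flag AR- and FOXA1-bound CREs and finalize classes
#'
#' A CRE is AR-bound iff it overlaps an AR ChIP peak at any time point by at
#' least one base (same rule for FOXA1). Non-promoter CREs become enhancers;
#' a promoter overlapping an AR peak keeps its promoter class with
#' `ar_bound = TRUE`. Adding peak sets can only flip flags FALSE -> TRUE.
#'
#' @param cres CRE table (promoters already assigned).
#' @param ar_peaks,foxa1_peaks An interval data.frame or a list of them (one
#'   per time point); `NULL` leaves the corresponding flag untouched.
#' @return The CRE table with `ar_bound`, `foxa1_bound` and `cre_class`
#'   filled in.
#' @export
classify_cres <- function(cres, ar_peaks = NULL, foxa1_peaks = NULL) {
  flag_overlap <- function(flags, peaks) {
    if (is.null(peaks)) return(flags)
    if (is.data.frame(peaks)) peaks <- list(peaks)
    gr_c <- cre_granges(cres)
    for (pk in peaks) {
      if (!nrow(pk)) next
      flags <- flags | IRanges::overlapsAny(gr_c, as_granges(pk))
    }
    flags
  }
  cres$ar_bound <- flag_overlap(cres$ar_bound, ar_peaks)
  cres$foxa1_bound <- flag_overlap(cres$foxa1_bound, foxa1_peaks)
  cres$cre_class[is.na(cres$cre_class)] <- "enhancer"
  cres
}

#' Label gene sets: hallmark membership, downregulation, expression quartiles
#'
#' Downregulation is called from the log2 fold change between a comparison
#' and a reference time point, `LFC = log2((e_cmp + eps) / (e_ref + eps))`,
#' with genes below the threshold flagged. Quartiles (Q1 = highest) come from
#' ranking the maximum expression over time; bin sizes differ by at most one.
#'
#' @param expression Gene-level data.frame with `gene` and `tpm_<label>`
#'   columns (sum isoform TPMs first if needed, see [gene_expression()]).
#' @param hallmark_genes Character vector of pathway (hallmark) gene ids
#'   treated as the regulated query set.
#' @param timepoints Time-point labels.
#' @param lfc_threshold Downregulation threshold on LFC (default -1).
#' @param t_ref,t_cmp Reference and comparison time points (defaults `0m`,
#'   `16h`, where the regulatory response is most marked).
#' @param pseudocount Expression pseudocount (default 0.01 TPM).
#' @return The expression table with `hallmark`, `lfc`, `downregulated`,
#'   `max_tpm`, `quartile` columns appended.
#' @export
define_gene_sets <- function(expression, hallmark_genes,
                             timepoints = default_timepoints(),
                             lfc_threshold = -1, t_ref = "0m", t_cmp = "16h",
                             pseudocount = 0.01) {
  tc <- tpm_cols(timepoints)
  missing_cols <- setdiff(tc, names(expression))
  if (length(missing_cols)) {
    stop("expression table missing column ", missing_cols[1], call. = FALSE)
  }
  g <- expression
  g$hallmark <- g$gene %in% hallmark_genes
  if (!any(g$hallmark)) {
    warning("no hallmark gene found in the expression table", call. = FALSE)
  }
  e_ref <- g[[paste0("tpm_", t_ref)]]
  e_cmp <- g[[paste0("tpm_", t_cmp)]]
  g$lfc <- log2((e_cmp + pseudocount) / (e_ref + pseudocount))
  g$downregulated <- g$lfc < lfc_threshold
  g$max_tpm <- do.call(pmax, g[tc])
  r <- rank(-g$max_tpm, ties.method = "first")
  g$quartile <- paste0("Q", ceiling(r * 4 / nrow(g)))
  g
}

#' Sum isoform expression to gene level
#' @param transcripts Transcript table with `gene` and `tpm_<label>` columns.
#' @param timepoints Time-point labels.
#' @return data.frame `gene` + per-timepoint summed TPM.
#' @export
gene_expression <- function(transcripts, timepoints = default_timepoints()) {
  tc <- tpm_cols(timepoints)
  agg <- rowsum(as.matrix(transcripts[tc]), group = transcripts$gene)
  out <- data.frame(gene = rownames(agg), stringsAsFactors = FALSE)
  out[tc] <- as.data.frame(agg)
  rownames(out) <- NULL
  out
}

#' Seeded sample of highly expressed background genes
#'
#' Backgrounds for fold-change comparisons: highly expressed genes outside
#' the hallmark set, drawn from the top expression quartiles.
#'
#' @param genes Output of [define_gene_sets()].
#' @param n Number of genes to draw (`Inf` for all eligible).
#' @param quartiles Quartile labels considered "highly expressed".
#' @param seed RNG seed for the draw.
#' @return Character vector of gene ids.
#' @export
sample_background_genes <- function(genes, n = 100,
                                    quartiles = c("Q1", "Q2"), seed = 7) {
  pool <- genes$gene[!genes$hallmark & genes$quartile %in% quartiles]
  if (!is.finite(n) || n >= length(pool)) return(pool)
  with_rng(seed, sample(pool, n))
}
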