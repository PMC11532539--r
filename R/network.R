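## The regulatory network: CREs as nodes, mark-specific loops as edges
## weighted by per-timepoint normalized contact frequency. Backed by a plain
## edge table keyed (node1, node2, mark) with one weight column per time
## point; node1 always sorts before node2 in the CRE coordinate order.

#' TMM-normalize the contact frequencies of a loop set
#'
#' Applies [tmm_normalize()] across the per-timepoint count columns of a
#' reference loop set, reducing between-timepoint library variation before
#' contact frequencies are compared.
#'
#' @param loop_set A `loop_set` from [read_loops()].
#' @return The loop set with normalized `cf_<label>` columns; the
#'   `tmm_result` is attached as `$tmm`.
#' @export
tmm_normalize_loops <- function(loop_set) {
  cols <- cf_cols(loop_set$timepoints)
  res <- tmm_normalize(as.matrix(loop_set$loops[cols]))
  loop_set$loops[cols] <- as.data.frame(res$normalized)
  loop_set$tmm <- res[c("factors", "ref_column", "lib_sizes")]
  loop_set
}

## Map anchor intervals onto CREs by maximal overlap (ties -> leftmost CRE).
## Returns an integer index into cres, NA when no CRE overlaps.
map_anchors <- function(chrom, start, end, cres) {
  gr_a <- GenomicRanges::GRanges(chrom,
                                 IRanges::IRanges(start = start + 1L, end = end))
  gr_c <- cre_granges(cres)
  ov <- GenomicRanges::findOverlaps(gr_a, gr_c)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  ow <- IRanges::width(IRanges::pintersect(IRanges::ranges(gr_a)[qh],
                                           IRanges::ranges(gr_c)[sh]))
  o <- order(qh, -ow, cres$start[sh])
  qh <- qh[o]; sh <- sh[o]
  keep <- !duplicated(qh)
  out <- rep(NA_integer_, length(chrom))
  out[qh[keep]] <- sh[keep]
  out
}

#' Build the regulatory network from reference loop sets
#'
#' Each anchor maps to the CRE with maximal overlap (ties to the leftmost
#' CRE). Loops with an unmapped anchor, or whose two anchors map to the same
#' CRE, are skipped and counted. Parallel loops collapsing onto the same
#' `(node1, node2, mark)` key have their per-timepoint counts summed. All
#' CREs are nodes, including isolated ones.
#'
#' @param loops A `loop_set` or list of loop sets (one per mark).
#' @param cres CRE table.
#' @return A `loop_network`: list with `nodes` (all CRE ids), `edges`
#'   (data.frame `node1`, `node2`, `mark`, `cf_<label>`), `timepoints`,
#'   `skip` (per-mark counts: `unmapped`, `self`, `collapsed`, plus the
#'   reader's skip counts), `n_input` rows per mark.
#' @export
build_network <- function(loops, cres) {
  if (inherits(loops, "loop_set")) loops <- list(loops)
  timepoints <- loops[[1]]$timepoints
  cre_rank <- order(order(cres$chrom, cres$start))  # coordinate rank per row
  edges_list <- list()
  skip <- list()
  n_input <- list()
  for (ls in loops) {
    stopifnot(identical(ls$timepoints, timepoints))
    df <- ls$loops
    mark <- ls$mark
    i1 <- map_anchors(df$chrom1, df$start1, df$end1, cres)
    i2 <- map_anchors(df$chrom2, df$start2, df$end2, cres)
    unmapped <- is.na(i1) | is.na(i2)
    self <- !unmapped & i1 == i2
    ok <- !unmapped & !self
    a <- i1[ok]; b <- i2[ok]
    swap <- cre_rank[b] < cre_rank[a]
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
    key <- paste0(cres$cre_id[a], "|", cres$cre_id[b])
    cf <- matrix(unlist(df[ok, cf_cols(timepoints), drop = FALSE]),
                 nrow = sum(ok), ncol = length(timepoints))
    agg <- if (sum(ok) > 0) {
      rowsum(cf, group = key, reorder = TRUE)
    } else {
      cf
    }
    colnames(agg) <- cf_cols(timepoints)
    first <- !duplicated(key)
    ord <- match(rownames(agg), key[first])
    ek <- data.frame(node1 = cres$cre_id[a[first]][ord],
                     node2 = cres$cre_id[b[first]][ord],
                     mark = rep_len(mark, nrow(agg)),
                     stringsAsFactors = FALSE)
    ek[cf_cols(timepoints)] <- as.data.frame(agg)
    edges_list[[mark]] <- ek
    skip[[mark]] <- c(list(unmapped = sum(unmapped), self = sum(self),
                           collapsed = sum(ok) - nrow(ek)),
                      ls$skip)
    n_input[[mark]] <- ls$n_input
  }
  edges <- do.call(rbind, edges_list)
  rownames(edges) <- NULL
  structure(list(nodes = cres$cre_id, edges = edges, timepoints = timepoints,
                 skip = skip, n_input = n_input),
            class = "loop_network")
}

#' @export
print.loop_network <- function(x, ...) {
  cat(sprintf("<loop_network> %d nodes, %d edges (%s), timepoints %s\n",
              length(x$nodes), nrow(x$edges),
              paste(sprintf("%s=%d", names(table(x$edges$mark)),
                            table(x$edges$mark)), collapse = " "),
              paste(x$timepoints, collapse = ",")))
  invisible(x)
}

#' Classify loops by the CRE classes of their endpoints
#'
#' @param network A `loop_network`.
#' @param cres CRE table with `cre_class` filled in.
#' @return data.frame `mark`, `class` (P-P / E-P / E-E), `n`, `fraction`;
#'   fractions sum to one within each mark.
#' @export
classify_loops <- function(network, cres) {
  cls <- cres$cre_class[match(network$edges$node1, cres$cre_id)]
  cls2 <- cres$cre_class[match(network$edges$node2, cres$cre_id)]
  n_prom <- (cls == "promoter") + (cls2 == "promoter")
  lab <- c("E-E", "E-P", "P-P")[n_prom + 1]
  tab <- as.data.frame(table(mark = network$edges$mark, class = lab),
                       stringsAsFactors = FALSE)
  names(tab)[3] <- "n"
  tab$fraction <- stats::ave(tab$n, tab$mark, FUN = function(v) v / sum(v))
  tab[order(tab$mark, tab$class), ]
}

#' First-degree neighbors of a viewpoint CRE
#'
#' @param network A `loop_network`.
#' @param viewpoint A CRE id present among the nodes.
#' @param mark Optional mark filter.
#' @return data.frame `neighbor`, `mark`, `cf_<label>`; zero rows for an
#'   isolated node.
#' @export
first_degree <- function(network, viewpoint, mark = NULL) {
  if (!viewpoint %in% network$nodes) {
    stop("unknown CRE id: ", viewpoint, call. = FALSE)
  }
  e <- network$edges
  if (!is.null(mark)) e <- e[e$mark == mark, , drop = FALSE]
  hit <- e$node1 == viewpoint | e$node2 == viewpoint
  e <- e[hit, , drop = FALSE]
  nb <- ifelse(e$node1 == viewpoint, e$node2, e$node1)
  out <- data.frame(neighbor = nb, mark = e$mark, stringsAsFactors = FALSE)
  out[cf_cols(network$timepoints)] <- e[cf_cols(network$timepoints)]
  rownames(out) <- NULL
  out
}

#' Mean coverage of a track over each CRE window
#'
#' Length-weighted mean of a bedGraph track over the fixed-width CRE window;
#' bases not covered by any track interval count as zero (bedGraph sparsity
#' convention). Track chromosomes absent from the CRE universe contribute
#' nothing (logged).
#'
#' @param track bedGraph data.frame from [read_bedgraph()].
#' @param cres CRE table.
#' @return Numeric vector of mean coverage, named by `cre_id`.
#' @export
aggregate_signal <- function(track, cres) {
  out <- stats::setNames(numeric(nrow(cres)), cres$cre_id)
  if (!nrow(track)) return(out)
  extra <- setdiff(unique(track$chrom), unique(cres$chrom))
  if (length(extra)) {
    message("track chromosome(s) not in CRE universe ignored: ",
            paste(extra, collapse = ","))
    track <- track[!track$chrom %in% extra, , drop = FALSE]
    if (!nrow(track)) return(out)
  }
  gr_t <- as_granges(track)
  gr_c <- cre_granges(cres)
  ov <- GenomicRanges::findOverlaps(gr_c, gr_t)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  w <- IRanges::width(IRanges::pintersect(IRanges::ranges(gr_c)[qh],
                                          IRanges::ranges(gr_t)[sh]))
  contrib <- rowsum(w * track$value[sh], group = qh)
  idx <- as.integer(rownames(contrib))
  out[idx] <- contrib[, 1] / (cres$end[idx] - cres$start[idx])
  out
}

#' Per-node loop counts (degree) at a time point or in the reference set
#'
#' A loop is "present" at a time point when its normalized contact frequency
#' exceeds `presence_threshold`; with `timepoint = NULL` the full reference
#' edge set is used.
#'
#' @param network A `loop_network`.
#' @param nodes CRE ids to report (default: all nodes).
#' @param mark Optional mark filter.
#' @param timepoint Optional time-point label.
#' @param presence_threshold Weight above which an edge counts as present.
#' @return data.frame `node`, `degree` (kernel-density-ready).
#' @export
loop_count_distribution <- function(network, nodes = NULL, mark = NULL,
                                    timepoint = NULL, presence_threshold = 0) {
  if (is.null(nodes)) nodes <- network$nodes
  if (!all(nodes %in% network$nodes)) {
    stop("unknown node id(s) in nodes", call. = FALSE)
  }
  e <- network$edges
  if (!is.null(mark)) e <- e[e$mark == mark, , drop = FALSE]
  if (!is.null(timepoint)) {
    e <- e[e[[paste0("cf_", timepoint)]] > presence_threshold, , drop = FALSE]
  }
  deg <- table(factor(c(e$node1, e$node2), levels = nodes))
  data.frame(node = nodes, degree = as.integer(deg), stringsAsFactors = FALSE)
}

#' Convert one mark/time-point layer of the network to an igraph graph
#'
#' @param network A `loop_network`.
#' @param mark Mark to extract.
#' @param timepoint Time point supplying the edge weight.
#' @return An igraph undirected graph with `weight` edge attribute.
#' @export
as_igraph <- function(network, mark, timepoint) {
  if (!requireNamespace("igraph", quietly = TRUE)) {
    stop("the igraph package is required for as_igraph()", call. = FALSE)
  }
  e <- network$edges[network$edges$mark == mark, , drop = FALSE]
  df <- data.frame(from = e$node1, to = e$node2,
                   weight = e[[paste0("cf_", timepoint)]])
  igraph::graph_from_data_frame(df, directed = FALSE,
                                vertices = network$nodes)
}
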