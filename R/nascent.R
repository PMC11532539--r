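## Nascent (capped RNA) TSS-proximal quantification: strand-appropriate
## maximum signal around each TSS, upregulation calls from LFC against the
## untreated time point, and assignment to maximal-expression time groups.

#' Maximum TSS-proximal nascent signal per transcript and time point
#'
#' The maximum track value within `half_window` bases of the TSS, taken from
#' the forward track for plus-strand transcripts and the reverse track for
#' minus-strand transcripts; zero when nothing overlaps. TSS positions are
#' 0-based; a base at distance exactly `half_window` is included, one base
#' further is not.
#'
#' @param fwd_tracks,rev_tracks Named lists (one bedGraph data.frame per
#'   time-point label) for the forward and reverse strand.
#' @param transcripts data.frame with `transcript`, `chrom`, `start`, `end`,
#'   `strand` (TSS derived strand-aware from the 0-based half-open interval).
#' @param timepoints Time-point labels (must all be present in both lists).
#' @param half_window Window half-width in bases (default 500).
#' @return Numeric matrix transcripts x timepoints (rownames = transcript).
#' @export
tss_signal <- function(fwd_tracks, rev_tracks, transcripts,
                       timepoints = default_timepoints(), half_window = 500) {
  missing_tp <- setdiff(timepoints, intersect(names(fwd_tracks),
                                              names(rev_tracks)))
  if (length(missing_tp)) {
    stop("missing track for time point ", missing_tp[1], call. = FALSE)
  }
  tss <- transcript_tss(transcripts$start, transcripts$end,
                        transcripts$strand)
  win <- GenomicRanges::GRanges(
    transcripts$chrom,
    IRanges::IRanges(start = tss - half_window + 1L,
                     end = tss + half_window + 1L))
  out <- matrix(0, nrow(transcripts), length(timepoints),
                dimnames = list(transcripts$transcript, timepoints))
  warned <- character(0)
  for (s in c("+", "-")) {
    rows <- which(transcripts$strand == s)
    if (!length(rows)) next
    tracks <- if (s == "+") fwd_tracks else rev_tracks
    for (t in timepoints) {
      track <- tracks[[t]]
      if (!nrow(track)) next
      absent <- setdiff(unique(transcripts$chrom[rows]), unique(track$chrom))
      warned <- union(warned, absent)
      ov <- GenomicRanges::findOverlaps(win[rows], as_granges(track))
      if (!length(ov)) next
      mx <- tapply(track$value[S4Vectors::subjectHits(ov)],
                   S4Vectors::queryHits(ov), max)
      out[rows[as.integer(names(mx))], t] <- as.numeric(mx)
    }
  }
  if (length(warned)) {
    message("transcript chromosome(s) absent from tracks (signal 0): ",
            paste(sort(warned), collapse = ","))
  }
  out
}

#' Call upregulated transcripts from nascent TSS signal
#'
#' `LFC_t = log2((s_t + eps) / (s_0m + eps))` against the reference time
#' point for every later time point; a transcript is upregulated when any
#' LFC exceeds 1.
#'
#' @param signal Matrix from [tss_signal()].
#' @param eps Signal pseudocount (default 0.5; nascent coverage is sparse
#'   and zero-TSS transcripts must not blow up the ratio).
#' @param ref Reference time-point label (default `0m`).
#' @return list with `lfc` (matrix over non-reference time points) and
#'   `upregulated` (named logical).
#' @export
classify_upregulated <- function(signal, eps = 0.5, ref = "0m") {
  if (!ref %in% colnames(signal)) {
    stop("reference time point ", ref, " missing from signal", call. = FALSE)
  }
  others <- setdiff(colnames(signal), ref)
  lfc <- log2((signal[, others, drop = FALSE] + eps) / (signal[, ref] + eps))
  up <- apply(lfc, 1, max) > 1
  list(lfc = lfc, upregulated = up)
}

#' Assign upregulated transcripts to maximal-expression time groups
#'
#' Each upregulated transcript's full time-course vector is z-scored (mean
#' 0, sample SD 1) and the transcript is assigned to the time point of the
#' maximal z (z-scoring never changes the argmax; it is retained as the
#' reported profile). Transcripts whose maximum falls at the reference time
#' point, or whose vector is constant, are dropped from grouping and
#' counted. Ties break toward the earlier time point.
#'
#' @param signal Matrix from [tss_signal()] (all time points).
#' @param upregulated Named logical from [classify_upregulated()].
#' @param ref Reference time point excluded from the groups.
#' @return list with `groups` (data.frame `transcript`, `group`),
#'   `dropped_constant`, `dropped_reference_max`, `z` (z-scored matrix).
#' @export
assign_time_group <- function(signal, upregulated, ref = "0m") {
  sel <- rownames(signal)[upregulated[rownames(signal)]]
  m <- signal[sel, , drop = FALSE]
  sds <- apply(m, 1, stats::sd)
  constant <- sds == 0
  z <- (m - rowMeans(m)) / ifelse(sds == 0, 1, sds)
  peak <- colnames(m)[max.col(z, ties.method = "first")]
  ref_max <- peak == ref & !constant
  keep <- !constant & !ref_max
  list(groups = data.frame(transcript = sel[keep], group = peak[keep],
                           stringsAsFactors = FALSE),
       dropped_constant = sum(constant),
       dropped_reference_max = sum(ref_max),
       z = z[keep, , drop = FALSE])
}
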