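## Readers/writers for the plain-text genomic formats the pipeline touches.
## All coordinates are kept 0-based half-open (BED native) internally; the
## only 1-based inputs are documented TSS columns, converted at parse time by
## the caller that owns them.

#' Read genomic intervals from BED or narrowPeak files
#'
#' Parses tab-separated interval files into the package's interval
#' data.frame (`chrom`, `start`, `end`, `name`, `summit`). `summit` is an
#' offset from `start` in bases; narrowPeak column 10 supplies it (a value of
#' -1, like plain BED, falls back to the midpoint convention).
#'
#' @param path File path.
#' @param format Either `"bed"` (3+ columns) or `"narrowPeak"` (10 columns).
#' @return data.frame with columns `chrom`, `start`, `end`, `name`, `summit`,
#'   rows in file order. Empty files yield an empty data.frame with a warning.
#' @export
read_intervals <- function(path, format = c("bed", "narrowPeak")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), summit = integer(),
                      stringsAsFactors = FALSE)
  if (file.size(path) == 0) {
    warning("empty interval file: ", path, call. = FALSE)
    return(empty)
  }
  dt <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                          colClasses = "character", data.table = FALSE)
  if (nrow(dt) == 0) {
    warning("empty interval file: ", path, call. = FALSE)
    return(empty)
  }
  need <- if (format == "narrowPeak") 10L else 3L
  ncol_ok <- rowSums(!is.na(dt) & dt != "") >= need
  if (any(!ncol_ok)) {
    stop(sprintf("malformed line %d in %s: expected >= %d columns",
                 which(!ncol_ok)[1], path, need), call. = FALSE)
  }
  start <- suppressWarnings(as.integer(dt[[2]]))
  end <- suppressWarnings(as.integer(dt[[3]]))
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad)) {
    stop(sprintf("malformed line %d in %s: need 0 <= start < end",
                 bad[1], path), call. = FALSE)
  }
  if (ncol(dt) >= 4 && !all(is.na(dt[[4]]) | dt[[4]] == "")) {
    name <- dt[[4]]
  } else {
    name <- sprintf("%s:%d-%d", dt[[1]], start, end)
  }
  mid <- (end - start) %/% 2L
  summit <- mid
  if (format == "narrowPeak") {
    s <- suppressWarnings(as.integer(dt[[10]]))
    bad <- which(is.na(s))
    if (length(bad)) {
      stop(sprintf("malformed line %d in %s: summit column not integer",
                   bad[1], path), call. = FALSE)
    }
    summit <- ifelse(s < 0, mid, s)
    bad <- which(summit >= end - start)
    if (length(bad)) {
      stop(sprintf("malformed line %d in %s: summit offset outside interval",
                   bad[1], path), call. = FALSE)
    }
  }
  data.frame(chrom = dt[[1]], start = start, end = end, name = name,
             summit = as.integer(summit), stringsAsFactors = FALSE)
}

#' Write intervals to BED or narrowPeak
#'
#' @param x Interval data.frame as returned by [read_intervals()].
#' @param path Output path.
#' @param format `"bed"` (chrom/start/end/name) or `"narrowPeak"` (10 column,
#'   summit offset in column 10).
#' @return `path`, invisibly.
#' @export
write_intervals <- function(x, path, format = c("bed", "narrowPeak")) {
  format <- match.arg(format)
  if (format == "bed") {
    out <- data.frame(x$chrom, x$start, x$end, x$name)
  } else {
    out <- data.frame(x$chrom, x$start, x$end, x$name, 0L, ".",
                      0, -1, -1, x$summit)
  }
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

loop_columns <- function(timepoints) {
  c("chrom1", "start1", "end1", "chrom2", "start2", "end2", "name", "mark",
    cf_cols(timepoints))
}

#' Read a per-timepoint loop table (BEDPE dialect)
#'
#' The dialect is BEDPE with a header row: six coordinate columns
#' (`chrom1,start1,end1,chrom2,start2,end2`), `name`, `mark`, then one
#' numeric contact-frequency column per time point named `cf_<label>`.
#' Anchors are canonicalized so that anchor1 sorts before anchor2 by
#' `(chrom, start)`. Inter-chromosomal records and records whose anchor
#' midpoints are closer than `min_span` or farther than `max_span` are
#' rejected and counted in the skip report rather than erroring.
#'
#' @param path File path.
#' @param timepoints Ordered time-point labels; one `cf_<label>` column per
#'   label must be present.
#' @param mark Optional mark label; when given it overrides/validates the
#'   file's `mark` column.
#' @param min_span,max_span Allowed anchor midpoint distance in bases
#'   (defaults mirror the 5 kb resolution / 3 Mb cap used when calling loops).
#' @return A `loop_set`: list with `loops` (data.frame), `mark`,
#'   `timepoints` and `skip` (named counts of rejected records).
#' @export
read_loops <- function(path, timepoints = default_timepoints(), mark = NULL,
                       min_span = 5000, max_span = 3e6) {
  assert_timepoints(timepoints)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, header = TRUE, sep = "\t", data.table = FALSE)
  need <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
  missing_cols <- setdiff(c(need, cf_cols(timepoints)), names(dt))
  if (length(missing_cols)) {
    stop("missing column ", missing_cols[1], " in ", path, call. = FALSE)
  }
  if (!"name" %in% names(dt)) dt$name <- sprintf("loop%d", seq_len(nrow(dt)))
  if (!"mark" %in% names(dt)) {
    if (is.null(mark)) stop("no mark column and no mark argument", call. = FALSE)
    dt$mark <- mark
  } else if (!is.null(mark)) {
    dt$mark <- mark
  }
  for (cc in cf_cols(timepoints)) {
    v <- suppressWarnings(as.numeric(dt[[cc]]))
    bad <- which(is.na(v) | v < 0)
    if (length(bad)) {
      stop(sprintf("non-numeric or negative count in column %s, row %d of %s",
                   cc, bad[1], path), call. = FALSE)
    }
    dt[[cc]] <- v
  }
  skip <- c(inter_chromosomal = 0L, out_of_range = 0L)
  inter <- dt$chrom1 != dt$chrom2
  skip["inter_chromosomal"] <- sum(inter)
  dt <- dt[!inter, , drop = FALSE]
  if (nrow(dt)) {
    mid1 <- (dt$start1 + dt$end1) / 2
    mid2 <- (dt$start2 + dt$end2) / 2
    span <- abs(mid2 - mid1)
    oor <- span < min_span | span > max_span
    skip["out_of_range"] <- sum(oor)
    dt <- dt[!oor, , drop = FALSE]
  }
  dt <- canonicalize_anchors(dt)
  structure(list(loops = dt,
                 mark = if (nrow(dt)) dt$mark[1] else mark,
                 timepoints = timepoints,
                 skip = as.list(skip),
                 n_input = nrow(dt) + sum(skip)),
            class = "loop_set")
}

## Swap anchors so anchor1 < anchor2 by (chrom, start); idempotent.
canonicalize_anchors <- function(dt) {
  if (!nrow(dt)) return(dt)
  swap <- dt$chrom2 < dt$chrom1 |
    (dt$chrom2 == dt$chrom1 & dt$start2 < dt$start1)
  if (any(swap)) {
    tmp <- dt[swap, c("chrom1", "start1", "end1")]
    dt[swap, c("chrom1", "start1", "end1")] <-
      dt[swap, c("chrom2", "start2", "end2")]
    dt[swap, c("chrom2", "start2", "end2")] <- tmp
  }
  dt
}

#' Write a loop set in the package's BEDPE dialect
#'
#' Numeric contact frequencies are written with full (17 significant digit)
#' precision so that a write/read round trip reproduces values exactly.
#'
#' @param x A `loop_set` (or its `loops` data.frame).
#' @param path Output path.
#' @param timepoints Time-point labels (defaults to the set's own).
#' @return `path`, invisibly.
#' @export
write_loops <- function(x, path, timepoints = NULL) {
  if (inherits(x, "loop_set")) {
    if (is.null(timepoints)) timepoints <- x$timepoints
    x <- x$loops
  }
  if (is.null(timepoints)) timepoints <- default_timepoints()
  cols <- loop_columns(timepoints)
  out <- x[, cols]
  for (cc in cf_cols(timepoints)) out[[cc]] <- sprintf("%.17g", out[[cc]])
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @export
print.loop_set <- function(x, ...) {
  cat(sprintf("<loop_set> mark=%s loops=%d timepoints=%s\n",
              x$mark, nrow(x$loops), paste(x$timepoints, collapse = ",")))
  skips <- unlist(x$skip)
  if (any(skips > 0)) {
    cat("  skipped:", paste(sprintf("%s=%d", names(skips), skips), collapse = " "), "\n")
  }
  invisible(x)
}

#' Read a typed TSV table against a column contract
#'
#' @param path TSV file with a header row.
#' @param schema Named character vector mapping required column names to one
#'   of `"character"`, `"numeric"`, `"integer"`, `"logical"`. Columns not in
#'   the schema are kept as character.
#' @return data.frame with typed columns, row order preserved.
#' @export
read_table <- function(path, schema) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, header = TRUE, sep = "\t",
                          colClasses = "character", data.table = FALSE,
                          na.strings = NULL)
  missing_cols <- setdiff(names(schema), names(dt))
  if (length(missing_cols)) {
    stop("missing column ", missing_cols[1], " in ", path, call. = FALSE)
  }
  for (col in names(schema)) {
    type <- schema[[col]]
    if (type == "character") next
    coerce <- switch(type,
                     numeric = as.numeric,
                     integer = as.integer,
                     logical = as.logical,
                     stop("unknown schema type: ", type, call. = FALSE))
    v <- suppressWarnings(coerce(dt[[col]]))
    bad <- which(is.na(v))
    if (length(bad)) {
      stop(sprintf("column %s of %s: value '%s' in row %d is not %s",
                   col, path, dt[[col]][bad[1]], bad[1], type), call. = FALSE)
    }
    dt[[col]] <- v
  }
  dt
}

#' Write a data.frame as TSV with full numeric precision
#' @param x data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  out <- x
  for (col in names(out)) {
    if (is.double(out[[col]])) out[[col]] <- sprintf("%.17g", out[[col]])
  }
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a 4-column bedGraph coverage track
#'
#' @param path File path.
#' @return data.frame `chrom`, `start`, `end`, `value` sorted by
#'   `(chrom, start)`. Missing bases mean zero coverage by convention.
#' @export
read_bedgraph <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), value = numeric()))
  }
  dt <- data.table::fread(path, header = FALSE, sep = "\t", data.table = FALSE,
                          col.names = c("chrom", "start", "end", "value"))
  if (!is.numeric(dt$value) || !is.numeric(dt$start) || !is.numeric(dt$end)) {
    stop("malformed bedGraph: ", path, call. = FALSE)
  }
  dt[order(dt$chrom, dt$start), , drop = FALSE]
}

write_bedgraph <- function(x, path) {
  x <- x[order(x$chrom, x$start), , drop = FALSE]
  out <- data.frame(x$chrom, x$start, x$end, sprintf("%.17g", x$value))
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}
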