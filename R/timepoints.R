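#' Default time-point labels of the stimulation time course
#'
#' The pipeline works with an ordered five-point time course: untreated
#' (`0m`) followed by 30 minutes, 4 hours, 16 hours and 72 hours of
#' stimulation. Every per-timepoint table in the package carries one column
#' per label, named `cf_<label>` (contact frequencies), `tpm_<label>`
#' (expression) or `sig_<label>` (coverage), in this order.
#'
#' @return Character vector of the five ordered labels.
#' @export
default_timepoints <- function() {
  c("0m", "30m", "4h", "16h", "72h")
}

cf_cols <- function(timepoints) paste0("cf_", timepoints)
tpm_cols <- function(timepoints) paste0("tpm_", timepoints)

assert_timepoints <- function(timepoints) {
  if (!is.character(timepoints) || length(timepoints) < 2 ||
      anyDuplicated(timepoints) > 0) {
    stop("timepoints must be >= 2 unique ordered labels", call. = FALSE)
  }
  invisible(timepoints)
}

## Evaluate `expr` under a private RNG stream seeded with `seed`, restoring
## the caller's RNG state afterwards. All stochastic operations in the
## package run through this so that no call mutates global reproducibility.
with_rng <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
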