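# Scalability instrumentation.  The driver never needs an all-pairs
# observation distance matrix; these counters let tests assert that GAP and
# Dunn evaluations stayed on subsamples and that no quadratic step ran.

.divikCounters <- new.env(parent = emptyenv())

.resetCountersState <- function() {
  assign("maxGapN", 0L, envir = .divikCounters)
  assign("maxDunnEvalN", 0L, envir = .divikCounters)
  assign("maxKmeansN", 0L, envir = .divikCounters)
  assign("maxPairwiseN", 0L, envir = .divikCounters)
}
.resetCountersState()

.noteCounter <- function(name, n) {
  cur <- get(name, envir = .divikCounters)
  if (n > cur) assign(name, as.integer(n), envir = .divikCounters)
  invisible(NULL)
}

#' Inspect or reset scalability counters
#'
#' The package records the largest problem sizes seen by its potentially
#' expensive steps: `maxGapN` (rows of any matrix a GAP statistic was
#' computed on), `maxDunnEvalN` (rows used in any Dunn evaluation),
#' `maxKmeansN` (rows of any K-means run) and `maxPairwiseN` (rows of any
#' all-pairs observation distance matrix; the pipeline computes none, so a
#' nonzero value flags a quadratic step).
#'
#' @return `divikCounters()`: a named integer vector of the four maxima.
#' @examples
#' resetDivikCounters()
#' divikCounters()
#' @export
divikCounters <- function() {
  c(maxGapN = get("maxGapN", envir = .divikCounters),
    maxDunnEvalN = get("maxDunnEvalN", envir = .divikCounters),
    maxKmeansN = get("maxKmeansN", envir = .divikCounters),
    maxPairwiseN = get("maxPairwiseN", envir = .divikCounters))
}

#' @rdname divikCounters
#' @export
resetDivikCounters <- function() {
  .resetCountersState()
  invisible(NULL)
}
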