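#' Accessors for popMDSA objects
#'
#' Small accessor functions so user code never reaches into slots.
#'
#' @param x a popMDSA object.
#' @return `trialTable()` the trial data.frame; `sessionTimeAxis()` the bin
#'   start times in seconds; `rateValues()` the trials x units x timepoints
#'   array; `accuracy()` per-timepoint accuracies; `decisionVectors()` the
#'   unit-norm DV matrix (columns = timepoints); `chanceThreshold()` the
#'   effective chance level; `groundTruth()` the embedded generator truth.
#' @name accessors
NULL

#' @rdname accessors
#' @export
trialTable <- function(x) {
  stopifnot(is(x, "SyntheticSession"))
  x@trials
}

#' @rdname accessors
#' @export
sessionTimeAxis <- function(x) {
  if (is(x, "SyntheticSession")) {
    cfg <- x@config
    seq(-cfg@itiDuration, cfg@stimDuration - cfg@binWidth, by = cfg@binWidth)
  } else if (is(x, "RateTensor")) x@timeAxis
  else if (is(x, "DecoderTimecourse")) x@timeAxis
  else stopf("no time axis for class '%s'", class(x)[1])
}

#' @rdname accessors
#' @export
rateValues <- function(x) {
  stopifnot(is(x, "RateTensor"))
  x@values
}

#' @rdname accessors
#' @export
accuracy <- function(x) {
  if (is(x, "DecoderTimecourse")) x@accuracy
  else if (is(x, "CrossTimeResult")) x@accuracy
  else stopf("no accuracy for class '%s'", class(x)[1])
}

#' @rdname accessors
#' @export
decisionVectors <- function(x) {
  if (is(x, "DecoderTimecourse")) x@dv
  else if (is(x, "CrossTimeResult")) x@dv
  else stopf("no decision vectors for class '%s'", class(x)[1])
}

#' @rdname accessors
#' @export
chanceThreshold <- function(x) {
  stopifnot(is(x, "DecoderTimecourse"))
  x@chance
}

#' @rdname accessors
#' @export
groundTruth <- function(x) {
  stopifnot(is(x, "SyntheticSession"))
  x@groundTruth
}

#' @rdname accessors
#' @export
basisMatrix <- function(x) {
  stopifnot(is(x, "SubspaceBasis"))
  x@D
}

#' @rdname accessors
#' @export
projectionOperator <- function(x) {
  stopifnot(is(x, "SubspaceBasis"))
  x@P
}

#' @rdname accessors
#' @export
displayBasis <- function(x) {
  stopifnot(is(x, "SubspaceBasis"))
  x@Q
}
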