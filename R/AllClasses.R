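#' @import methods
NULL

#' Configuration of a synthetic two-context session
#'
#' Describes the trial structure, the Poisson population model and the
#' movement streams of a simulated blocked two-context go/no-go session.
#' Create instances with [sessionConfig()]; the validity method enforces the
#' parameter domains (positive durations, unit-norm modulation directions,
#' probabilities in \[0, 1\]).
#'
#' @slot nTrialsPerContext number of multimodal trials per context block.
#' @slot stimDuration,itiDuration,timeoutExtra,binWidth timing, seconds.
#' @slot nUnits number of units in the population.
#' @slot baselineRates per-unit baseline firing rates, Hz.
#' @slot modulation named list of modulation components; each component is a
#'   list with elements `variable` (one of `"context"`, `"visual"`,
#'   `"audio"`, `"choice"`, `"speed"`), `direction` (unit-norm vector over
#'   units), `amplitude` (Hz), `profile` (`"sustained"`, `"stimulus"` or a
#'   numeric time weighting) and `rotate` (logical; whether the component's
#'   direction undergoes the onset rotation).
#' @slot onsetRotationAngle degrees; planar rotation applied to rotating
#'   components at stimulus onset.
#' @slot rotationPartner unit vector spanning the rotation plane together
#'   with the rotating direction.
#' @slot choiceStrategy list with `name` and optional `param`.
#' @slot speedContextCoupling dimensionless in \[0, 1\].
#' @slot speedSpec list: `base`, `delta` (cm/s context offset at coupling 1),
#'   `sd`, `ar` (AR(1) coefficient of the speed trace).
#' @slot videoSpec list: `make`, `width`, `height`, `fps`, `dotSigma` (px),
#'   `noiseSd`.
#' @slot seed integer master seed.
#' @export
setClass("SessionConfig", representation(
  nTrialsPerContext = "numeric",
  stimDuration = "numeric",
  itiDuration = "numeric",
  timeoutExtra = "numeric",
  binWidth = "numeric",
  nUnits = "numeric",
  baselineRates = "numeric",
  modulation = "list",
  onsetRotationAngle = "numeric",
  rotationPartner = "numeric",
  choiceStrategy = "list",
  speedContextCoupling = "numeric",
  speedSpec = "list",
  videoSpec = "list",
  seed = "numeric"
))

setValidity("SessionConfig", function(object) {
  msgs <- character()
  chk <- function(ok, field, what)
    if (!isTRUE(ok)) msgs <<- c(msgs, sprintf("configuration error in '%s': %s", field, what))
  chk(length(object@nTrialsPerContext) == 1 && object@nTrialsPerContext >= 1,
      "nTrialsPerContext", "must be a count >= 1")
  for (f in c("stimDuration", "itiDuration", "binWidth"))
    chk(length(slot(object, f)) == 1 && slot(object, f) > 0, f, "must be > 0")
  chk(object@timeoutExtra >= 0, "timeoutExtra", "must be >= 0")
  chk(length(object@nUnits) == 1 && object@nUnits >= 1, "nUnits", "must be a count >= 1")
  chk(length(object@baselineRates) == object@nUnits && all(object@baselineRates >= 0),
      "baselineRates", "must be nonnegative, one per unit")
  for (i in seq_along(object@modulation)) {
    m <- object@modulation[[i]]
    nm <- names(object@modulation)[i]
    chk(is.list(m) && all(c("variable", "direction", "amplitude") %in% names(m)),
        paste0("modulation$", nm), "needs variable, direction, amplitude")
    if (!is.list(m) || !all(c("variable", "direction", "amplitude") %in% names(m))) next
    chk(m$variable %in% c("context", "visual", "audio", "choice", "speed"),
        paste0("modulation$", nm, "$variable"), "unknown task variable")
    chk(length(m$direction) == object@nUnits &&
          abs(sqrt(sum(m$direction^2)) - 1) < 1e-6,
        paste0("modulation$", nm, "$direction"), "must be a unit vector over units")
    chk(length(m$amplitude) == 1 && m$amplitude >= 0,
        paste0("modulation$", nm, "$amplitude"), "must be >= 0")
  }
  chk(object@onsetRotationAngle >= 0 && object@onsetRotationAngle <= 180,
      "onsetRotationAngle", "must lie in [0, 180] degrees")
  strat <- object@choiceStrategy
  chk(is.list(strat) && !is.null(strat$name) && strat$name %in%
        c("context_aware", "context_aware_bias", "context_aware_lapse",
          "context_unaware_rate", "opposite_modality"),
      "choiceStrategy", "unknown strategy name")
  if (!is.null(strat$param))
    chk(strat$param >= 0 && strat$param <= 1, "choiceStrategy$param", "must lie in [0, 1]")
  chk(length(object@speedContextCoupling) == 1 &&
        object@speedContextCoupling >= 0 && object@speedContextCoupling <= 1,
      "speedContextCoupling", "must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' A fully simulated session
#'
#' Container produced by [generateSession()]: trial table, per-unit per-trial
#' spike times, run-speed traces, optional video frames, and the embedded
#' ground truth (directions, amplitudes, strategy parameters).
#'
#' @slot trials data.frame, one row per trial (see [classifyTrials()] for the
#'   column schema).
#' @slot spikes list over units of lists over trials of spike-time vectors,
#'   seconds relative to stimulus onset.
#' @slot speed trials x timepoints matrix, cm/s, on the session bin grid.
#' @slot speedTime time axis of `speed`, seconds.
#' @slot frames `height x width x frames` array of 8-bit grayscale values, or
#'   a 0-extent array when video was not requested.
#' @slot groundTruth list of embedded parameters.
#' @slot config the [SessionConfig-class] used.
#' @export
setClass("SyntheticSession", representation(
  trials = "data.frame",
  spikes = "list",
  speed = "matrix",
  speedTime = "numeric",
  frames = "array",
  groundTruth = "list",
  config = "SessionConfig"
))

setValidity("SyntheticSession", function(object) {
  cfg <- object@config
  lo <- -cfg@itiDuration
  hi <- cfg@stimDuration
  for (u in seq_along(object@spikes)) for (tr in seq_along(object@spikes[[u]])) {
    st <- object@spikes[[u]][[tr]]
    if (length(st) && (min(st) < lo - 1e-9 || max(st) > hi + 1e-9))
      return(sprintf("spike times of unit %d, trial %d outside the trial window", u, tr))
  }
  if (length(object@frames) &&
      (min(object@frames) < 0 || max(object@frames) > 255))
    return("frames must hold 8-bit grayscale values in [0, 255]")
  TRUE
})

#' Trials x units x timepoints rate tensor
#'
#' Instantaneous firing rates at 10-ms resolution, either in Hz (output of
#' [estimateRates()]) or baseline-standardized z-units (output of
#' [zscoreBaseline()]).
#'
#' @slot values numeric array, trials x units x timepoints.
#' @slot timeAxis bin start times, seconds relative to stimulus onset.
#' @slot scale `"Hz"` or `"z"`.
#' @slot baselineWindow seconds, the window whose time-averaged activity
#'   defines the z-score center.
#' @slot unitsDropped data.frame with columns `unit` and `reason`.
#' @export
setClass("RateTensor", representation(
  values = "array",
  timeAxis = "numeric",
  scale = "character",
  baselineWindow = "numeric",
  unitsDropped = "data.frame"
))

setValidity("RateTensor", function(object) {
  d <- dim(object@values)
  if (length(d) != 3) return("values must be a 3-d array (trials x units x timepoints)")
  if (d[3] != length(object@timeAxis)) return("timeAxis length must match dim 3")
  steps <- diff(object@timeAxis)
  if (length(steps) && any(abs(steps - steps[1]) > 1e-9))
    return("timeAxis must be uniform")
  if (anyNA(object@values)) return("values must not contain NA for retained units")
  TRUE
})

#' Time-resolved cross-validated decoder result
#'
#' @slot variable decoded task variable.
#' @slot timeAxis timepoints at which decoders were trained (feature-window
#'   start times), seconds.
#' @slot accuracy mean held-out accuracy per timepoint.
#' @slot sem one standard error of the fold means per timepoint.
#' @slot dv unit-norm decision vectors, one column per timepoint (feature
#'   space collapsed to the projected/unit space by within-unit averaging).
#' @slot dvRaw same vectors before normalization (fold-averaged
#'   coefficients); these are what window-averaging for [decisionVector()]
#'   consumes.
#' @slot folds number of CV folds.
#' @slot nTrials number of trials used.
#' @slot chance effective chance threshold ([chanceBaseline()]), or NA.
#' @export
setClass("DecoderTimecourse", representation(
  variable = "character",
  timeAxis = "numeric",
  accuracy = "numeric",
  sem = "numeric",
  dv = "matrix",
  dvRaw = "matrix",
  folds = "numeric",
  nTrials = "numeric",
  chance = "numeric"
))

setValidity("DecoderTimecourse", function(object) {
  if (any(object@accuracy < -1e-9 | object@accuracy > 1 + 1e-9))
    return("accuracies must lie in [0, 1]")
  nrm <- sqrt(colSums(object@dv^2))
  if (any(abs(nrm - 1) > 1e-6)) return("decision vectors must be unit-norm")
  TRUE
})

#' Cross-temporal generalization result
#'
#' @slot variable decoded task variable.
#' @slot trainTimes,testTimes seconds.
#' @slot accuracy trainTimes x testTimes matrix of held-out accuracies.
#' @slot dv unit-norm decision vectors per training time (columns).
#' @slot nTrials trials used.
#' @export
setClass("CrossTimeResult", representation(
  variable = "character",
  trainTimes = "numeric",
  testTimes = "numeric",
  accuracy = "matrix",
  dv = "matrix",
  nTrials = "numeric"
))

#' Task-relevant subspace spanned by decision vectors
#'
#' Holds the (possibly skewed) DV basis `D`, the oblique projection operator
#' `P = D (D'D)^-1 D'` and the Gram-Schmidt orthonormalization `Q` used as
#' display coordinates (standardized units).
#'
#' @slot D units x K matrix of unit-norm, linearly independent DVs.
#' @slot P units x units projection operator.
#' @slot Q units x K orthonormal display basis.
#' @slot conditionNumber condition number of D.
#' @export
setClass("SubspaceBasis", representation(
  D = "matrix", P = "matrix", Q = "matrix", conditionNumber = "numeric"
))

setValidity("SubspaceBasis", function(object) {
  P <- object@P
  if (max(abs(P %*% P - P)) > 1e-8) return("P must be idempotent")
  if (max(abs(P - t(P))) > 1e-8) return("P must be symmetric")
  if (max(abs(crossprod(object@Q) - diag(ncol(object@Q)))) > 1e-8)
    return("Q must have orthonormal columns")
  TRUE
})

setMethod("show", "SessionConfig", function(object) {
  cat("SessionConfig:", object@nTrialsPerContext, "trials/context,",
      object@nUnits, "units\n")
  cat("  stimulus", object@stimDuration, "s, ITI", object@itiDuration,
      "s, bin", object@binWidth * 1000, "ms\n")
  cat("  modulation:", if (length(object@modulation))
    paste(sprintf("%s(%s, %.3g Hz)", names(object@modulation),
                  vapply(object@modulation, `[[`, "", "variable"),
                  vapply(object@modulation, `[[`, 0, "amplitude")),
          collapse = ", ") else "none", "\n")
  cat("  choice strategy:", object@choiceStrategy$name,
      if (!is.null(object@choiceStrategy$param))
        sprintf("(param = %g)", object@choiceStrategy$param) else "", "\n")
  cat("  speed-context coupling:", object@speedContextCoupling,
      " onset rotation:", object@onsetRotationAngle, "deg\n")
})

setMethod("show", "SyntheticSession", function(object) {
  cat("SyntheticSession:", nrow(object@trials), "trials,",
      length(object@spikes), "units",
      if (length(object@frames)) sprintf(", %d video frames", dim(object@frames)[3])
      else "", "\n")
  print(object@config)
})

setMethod("show", "RateTensor", function(object) {
  d <- dim(object@values)
  cat(sprintf("RateTensor (%s): %d trials x %d units x %d timepoints [%g, %g] s\n",
              object@scale, d[1], d[2], d[3],
              min(object@timeAxis), max(object@timeAxis)))
  if (nrow(object@unitsDropped))
    cat("  dropped units:", paste(object@unitsDropped$unit, collapse = ", "), "\n")
})

setMethod("show", "DecoderTimecourse", function(object) {
  cat(sprintf("DecoderTimecourse '%s': %d timepoints, %d trials, %d-fold CV\n",
              object@variable, length(object@timeAxis), object@nTrials,
              as.integer(object@folds)))
  cat(sprintf("  accuracy %.3f-%.3f (mean %.3f)",
              min(object@accuracy), max(object@accuracy), mean(object@accuracy)))
  if (!is.na(object@chance)) cat(sprintf(", chance threshold %.3f", object@chance))
  cat("\n")
})

setMethod("show", "CrossTimeResult", function(object) {
  cat(sprintf("CrossTimeResult '%s': %d train x %d test times, %d trials\n",
              object@variable, length(object@trainTimes),
              length(object@testTimes), object@nTrials))
})

setMethod("show", "SubspaceBasis", function(object) {
  cat(sprintf("SubspaceBasis: %d-dimensional subspace of %d units (cond. %.3g)\n",
              ncol(object@D), nrow(object@D), object@conditionNumber))
})
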