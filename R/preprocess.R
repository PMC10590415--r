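#' Instantaneous firing rates from spikes
#'
#' Bins spikes in 10-ms windows and convolves the counts with a unit-mass
#' symmetric Gaussian kernel (default sigma = 100 ms, truncated at +-4 sigma
#' and renormalized, including near trial edges where no padding is used),
#' scaled to Hz.
#'
#' @param x a [SyntheticSession-class], or a trials x units x timepoints
#'   counts array (then `timeAxis` is required).
#' @param sigma kernel width, seconds.
#' @param timeAxis bin start times for array input.
#' @param binWidth bin width, seconds.
#' @return a [RateTensor-class] in Hz.
#' @export
estimateRates <- function(x, sigma = 0.100, timeAxis = NULL, binWidth = 0.010) {
  if (sigma <= 0) stopf("sigma must be positive")
  if (is(x, "SyntheticSession")) {
    timeAxis <- sessionTimeAxis(x)
    binWidth <- x@config@binWidth
    counts <- binSpikes(x)
  } else {
    counts <- x
    if (is.null(timeAxis)) stopf("timeAxis is required for array input")
  }
  d <- dim(counts)
  W <- gaussian_kernel_matrix(d[3], binWidth, sigma)
  flat <- matrix(aperm(counts, c(3, 1, 2)), d[3], d[1] * d[2])
  sm <- (W %*% flat) / binWidth
  vals <- aperm(array(sm, dim = c(d[3], d[1], d[2])), c(2, 3, 1))
  new("RateTensor", values = vals, timeAxis = timeAxis, scale = "Hz",
      baselineWindow = c(NA_real_, NA_real_),
      unitsDropped = data.frame(unit = integer(0), reason = character(0)))
}

#' Baseline z-scoring of a rate tensor
#'
#' Per unit, subtracts the across-trial mean of the baseline-window
#' time-averaged activity and divides by the standard deviation of the
#' unit's rates pooled over all trials and all timepoints of the trial.
#' Units with (numerically) zero pooled variance are dropped and listed with
#' reason `"degenerate_std"`.
#'
#' @param rates a [RateTensor-class] in Hz.
#' @param baselineWindow seconds relative to stimulus onset (default
#'   \[-1.5, 0\)).
#' @return a [RateTensor-class] in z-units.
#' @export
zscoreBaseline <- function(rates, baselineWindow = c(-1.5, 0)) {
  stopifnot(is(rates, "RateTensor"))
  tax <- rates@timeAxis
  base_idx <- which(tax >= baselineWindow[1] & tax < baselineWindow[2])
  if (!length(base_idx)) stopf("baseline window outside the time axis")
  v <- rates@values
  nU <- dim(v)[2]
  mu <- apply(v[, , base_idx, drop = FALSE], 2, mean)
  sd_all <- apply(v, 2, stats::sd)
  keep <- sd_all > 1e-12
  if (!any(keep)) stopf("all units have zero variance")
  dropped <- data.frame(unit = which(!keep),
                        reason = rep("degenerate_std", sum(!keep)))
  out <- v[, keep, , drop = FALSE]
  for (u in seq_len(sum(keep)))
    out[, u, ] <- (out[, u, ] - mu[keep][u]) / sd_all[keep][u]
  new("RateTensor", values = out, timeAxis = tax, scale = "z",
      baselineWindow = baselineWindow, unitsDropped = dropped)
}

#' Per-unit sensitivity to a binary task variable
#'
#' For each unit and timepoint, the absolute difference between the mean
#' rates at the two variable values divided by the standard deviation of the
#' unit's rates over all trials at that timepoint, averaged over the epoch's
#' timepoints. Reported separately for the pre-stimulus and on-stimulus
#' epochs.
#'
#' @param rates a [RateTensor-class].
#' @param labels binary (0/1) vector, one per trial.
#' @param epochs named list of time windows, seconds.
#' @return units x epochs matrix of sensitivities.
#' @export
sensitivityIndex <- function(rates, labels,
                             epochs = list(pre = c(-1.5, 0), on = c(0, 3))) {
  stopifnot(is(rates, "RateTensor"))
  if (length(unique(stats::na.omit(labels))) != 2)
    stopf("labels must take exactly two values")
  v <- rates@values
  keep <- !is.na(labels)
  v <- v[keep, , , drop = FALSE]
  labels <- labels[keep]
  g1 <- labels == max(labels)
  m1 <- apply(v[g1, , , drop = FALSE], c(2, 3), mean)
  m0 <- apply(v[!g1, , , drop = FALSE], c(2, 3), mean)
  s <- apply(v, c(2, 3), stats::sd)
  sens_t <- abs(m1 - m0) / s
  sens_t[s < 1e-12] <- 0
  tax <- rates@timeAxis
  out <- vapply(epochs, function(w) {
    idx <- which(tax >= w[1] & tax < w[2])
    rowMeans(sens_t[, idx, drop = FALSE])
  }, numeric(dim(v)[2]))
  out
}
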