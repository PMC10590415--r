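#' Baseline-standardized rate tensor of a session
#'
#' Convenience pipeline: bin spikes, Gaussian-smooth to instantaneous rates,
#' z-score against the pre-stimulus baseline.
#'
#' @param session a [SyntheticSession-class].
#' @param sigma smoothing kernel width, seconds.
#' @param baselineWindow seconds.
#' @return a [RateTensor-class] in z-units.
#' @export
sessionRates <- function(session, sigma = 0.100, baselineWindow = c(-1.5, 0)) {
  zscoreBaseline(estimateRates(session, sigma = sigma), baselineWindow)
}

#' Per-trial feature block at one timepoint
#'
#' Concatenates, for each unit, `nBins` consecutive 10-ms activity bins
#' spanning the window `[t, t + nBins * 10 ms)`, unit-major (all bins of
#' unit 1, then unit 2, ...). With a `projector` (rows x units), activity is
#' projected bin-wise first and the features are component-major.
#'
#' @param x a [RateTensor-class] or trials x units x timepoints array.
#' @param t window start time, seconds (must be on the time axis).
#' @param nBins number of bins (default 5, a 50-ms window).
#' @param timeAxis required for array input.
#' @param projector optional K x units projection matrix.
#' @return trials x (nBins * K) feature matrix.
#' @export
buildFeatures <- function(x, t, nBins = 5, timeAxis = NULL, projector = NULL) {
  if (is(x, "RateTensor")) {
    timeAxis <- x@timeAxis
    v <- x@values
  } else v <- x
  i <- which(abs(timeAxis - t) < 1e-9)
  if (length(i) != 1 || i + nBins - 1 > length(timeAxis))
    stopf("feature window [%g, %g) is outside the time axis", t,
          t + nBins * mean(diff(timeAxis)))
  m <- v[, , i:(i + nBins - 1), drop = FALSE]
  if (!is.null(projector)) {
    d <- dim(m)
    pm <- array(0, dim = c(d[1], nrow(projector), d[3]))
    for (b in seq_len(d[3])) pm[, , b] <- m[, , b] %*% t(projector)
    m <- pm
  }
  matrix(aperm(m, c(1, 3, 2)), dim(m)[1], dim(m)[2] * dim(m)[3])
}

# core CV decode of one feature block under a given fold assignment;
# returns per-fold accuracies and the fold-averaged coefficient vector
decode_block <- function(F, y, foldid) {
  ks <- sort(unique(foldid))
  acc <- numeric(length(ks))
  beta <- 0
  for (i in seq_along(ks)) {
    te <- foldid == ks[i]
    fit <- ridge_logistic(F[!te, , drop = FALSE], y[!te])
    acc[i] <- mean(predict_ridge(fit, F[te, , drop = FALSE]) == y[te])
    beta <- beta + fit$beta / length(ks)
  }
  list(acc = acc, beta = beta)
}

# collapse a feature-space coefficient vector (nBins per unit/component)
# back to the unit/component space by within-unit averaging
collapse_beta <- function(beta, nBins) {
  colMeans(matrix(beta, nrow = nBins))
}

unit_norm <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stopf("zero decision vector")
  v / n
}

# resolve (rates, labels) from a session or a rate tensor
decoding_input <- function(x, variable = NULL, labels = NULL,
                           trialFilter = NULL, rates = NULL) {
  if (is(x, "SyntheticSession")) {
    trials <- x@trials
    if (is.null(rates)) rates <- sessionRates(x)
    if (is.null(labels)) labels <- labels_for(trials, variable)
    keep <- rep(TRUE, nrow(trials))
    if (!is.null(trialFilter)) {
      keep <- if (is.function(trialFilter)) trialFilter(trials) else trialFilter
      if (!any(keep)) stopf("trial filter removed all trials")
    }
    keep <- keep & !is.na(labels)
    if (length(unique(labels[keep])) < 2)
      stopf("a class is absent after applying the trial filter for '%s'",
            if (is.null(variable)) "labels" else variable)
    list(rates = rates, labels = labels[keep], keep = keep,
         variable = if (is.null(variable)) "labels" else variable)
  } else {
    keep <- !is.na(labels)
    if (length(unique(labels[keep])) < 2) stopf("labels contain a single class")
    list(rates = x, labels = labels[keep], keep = keep,
         variable = if (is.null(variable)) "labels" else variable)
  }
}

subset_trials <- function(rates, keep) {
  if (is(rates, "RateTensor")) {
    out <- rates
    out@values <- rates@values[keep, , , drop = FALSE]
    out
  } else rates[keep, , , drop = FALSE]
}

valid_timepoints <- function(timeAxis, nBins) {
  timeAxis[seq_len(length(timeAxis) - nBins + 1)]
}

#' Time-resolved cross-validated linear decoding
#'
#' Trains a separate L2-regularized logistic decoder at every timepoint on
#' 50-ms feature blocks with class-stratified k-fold cross-validation, and
#' reports held-out accuracy (mean and s.e.m. over folds) plus the unit-norm
#' decision vector per timepoint.
#'
#' @param x a [SyntheticSession-class] or a [RateTensor-class] /
#'   trials x units x timepoints array.
#' @param variable task variable to decode (session input): `"context"`,
#'   `"visual"`, `"audio"` or `"choice"`.
#' @param labels explicit 0/1 labels (tensor input, or to override).
#' @param trialFilter logical vector or function of the trial table.
#' @param timepoints training times; defaults to every valid 10-ms timepoint.
#' @param nBins feature bins per unit (default 5).
#' @param folds number of CV folds (default 10) or `"loo"`.
#' @param seed integer seed for the fold assignment.
#' @param projector optional K x units matrix; decoding then operates on the
#'   projected activity (used for subspace and nullspace decoding).
#' @param rates optional precomputed [RateTensor-class] for session input.
#' @return a [DecoderTimecourse-class].
#' @export
decodeTimecourse <- function(x, variable = NULL, labels = NULL,
                             trialFilter = NULL, timepoints = NULL,
                             nBins = 5, folds = 10, seed = 1,
                             projector = NULL, rates = NULL) {
  inp <- decoding_input(x, variable, labels, trialFilter, rates)
  rt <- subset_trials(inp$rates, inp$keep)
  y <- inp$labels
  tax <- if (is(rt, "RateTensor")) rt@timeAxis else
    stop("array input needs a RateTensor")
  if (is.null(timepoints)) timepoints <- valid_timepoints(tax, nBins)
  loo <- identical(folds, "loo")
  k <- if (loo) length(y) else folds
  if (!loo && min(table(y)) < 2 * k)
    stopf("need >= 2 trials per class per fold (have %d for %d folds)",
          min(table(y)), k)
  foldid <- with_seed(seed, if (loo) seq_along(y) else stratified_folds(y, k))
  nt <- length(timepoints)
  acc <- sem <- numeric(nt)
  dvr <- NULL
  for (i in seq_len(nt)) {
    F <- buildFeatures(rt, timepoints[i], nBins, projector = projector)
    db <- decode_block(F, y, foldid)
    acc[i] <- mean(db$acc)
    sem[i] <- stats::sd(db$acc) / sqrt(length(db$acc))
    cb <- collapse_beta(db$beta, nBins)
    if (is.null(dvr)) dvr <- matrix(0, length(cb), nt)
    dvr[, i] <- cb
  }
  dv <- matrix(apply(dvr, 2, unit_norm), nrow = nrow(dvr))
  new("DecoderTimecourse", variable = inp$variable, timeAxis = timepoints,
      accuracy = acc, sem = sem, dv = dv, dvRaw = dvr,
      folds = k, nTrials = length(y), chance = NA_real_)
}

#' Effective chance level from shuffled-label decoders
#'
#' Repeats the full cross-validated decoding with labels drawn from a
#' Bernoulli(0.5) distribution. Each run contributes the time-averaged
#' (fold mean + 1 s.e.m.); the threshold is the mean + 1 s.e.m. of those run
#' values — a one-sided effective chance level.
#'
#' @inheritParams decodeTimecourse
#' @param nRuns number of randomized runs (default 40).
#' @param nTrials number of trials (defaults to the input's trial count).
#' @return list with `threshold` and the per-run values `runs`.
#' @export
chanceBaseline <- function(x, nRuns = 40, timepoints = NULL, nBins = 5,
                           folds = 10, seed = 1, projector = NULL,
                           nTrials = NULL, rates = NULL) {
  rt <- if (is(x, "SyntheticSession")) {
    if (is.null(rates)) rates <- sessionRates(x)
    rates
  } else x
  n_all <- dim(rt@values)[1]
  if (is.null(nTrials)) nTrials <- n_all
  loo <- identical(folds, "loo")
  runs <- with_seed(seed, {
    vapply(seq_len(nRuns), function(r) {
      keep <- if (nTrials < n_all) sample.int(n_all, nTrials) else seq_len(n_all)
      repeat {
        y <- stats::rbinom(nTrials, 1, 0.5)
        if (min(table(factor(y, levels = 0:1))) >= (if (loo) 2 else 2 * folds)) break
      }
      tc <- decodeTimecourse(subset_trials(rt, keep), labels = y,
                             timepoints = timepoints, nBins = nBins,
                             folds = folds, seed = sample.int(1e6, 1),
                             projector = projector)
      mean(tc@accuracy + tc@sem)
    }, 0)
  })
  list(threshold = mean(runs) + stats::sd(runs) / sqrt(nRuns), runs = runs)
}

#' Cross-temporal generalization decoding
#'
#' Decoders trained at each training timepoint are tested at every testing
#' timepoint on held-out trials, with a cross-validation scheme of `nSplits`
#' randomized stratified 3:1 train/test splits (accuracies averaged over
#' splits).
#'
#' @inheritParams decodeTimecourse
#' @param trainTimes,testTimes timepoint grids (default: all valid
#'   timepoints).
#' @param nSplits number of randomized splits (default 2).
#' @param trainFrac training fraction (default 0.75).
#' @return a [CrossTimeResult-class].
#' @export
crossTimeDecode <- function(x, variable = NULL, labels = NULL,
                            trialFilter = NULL, trainTimes = NULL,
                            testTimes = NULL, nSplits = 2, trainFrac = 0.75,
                            nBins = 5, seed = 1, projector = NULL,
                            rates = NULL) {
  inp <- decoding_input(x, variable, labels, trialFilter, rates)
  rt <- subset_trials(inp$rates, inp$keep)
  y <- inp$labels
  tax <- rt@timeAxis
  if (is.null(trainTimes)) trainTimes <- valid_timepoints(tax, nBins)
  if (is.null(testTimes)) testTimes <- trainTimes
  Ftest_all <- lapply(testTimes, function(t)
    buildFeatures(rt, t, nBins, projector = projector))
  acc <- matrix(0, length(trainTimes), length(testTimes))
  dvr <- NULL
  with_seed(seed, {
    for (s in seq_len(nSplits)) {
      te <- logical(length(y))
      for (cls in unique(y)) {
        idx <- which(y == cls)
        te[sample(idx, max(1, round((1 - trainFrac) * length(idx))))] <- TRUE
      }
      for (i in seq_along(trainTimes)) {
        Ftr <- buildFeatures(rt, trainTimes[i], nBins, projector = projector)
        fit <- ridge_logistic(Ftr[!te, , drop = FALSE], y[!te])
        cb <- collapse_beta(fit$beta, nBins)
        if (is.null(dvr)) dvr <- matrix(0, length(cb), length(trainTimes))
        dvr[, i] <- dvr[, i] + cb / nSplits
        for (j in seq_along(testTimes))
          acc[i, j] <- acc[i, j] +
            mean(predict_ridge(fit, Ftest_all[[j]][te, , drop = FALSE]) ==
                   y[te]) / nSplits
      }
    }
  })
  new("CrossTimeResult", variable = inp$variable, trainTimes = trainTimes,
      testTimes = testTimes, accuracy = acc,
      dv = matrix(apply(dvr, 2, unit_norm), nrow = nrow(dvr)),
      nTrials = length(y))
}

#' Decay rates, DV-angle matrix and block statistics of a cross-time result
#'
#' Computes (i) the accuracy decay rate at each training time — minus the
#' slope of a linear fit over the first `decaySpan` of forward test shifts,
#' in accuracy loss per 100 ms; (ii) the symmetric DV-angle matrix
#' `gamma[t1, t2] = arccos(d(t1) . d(t2))` in degrees; (iii) mean accuracy
#' and mean angle within the pre-stimulus block, within the on-stimulus
#' block (lower triangles) and across the pre/on border (full rectangle),
#' all excluding elements with `|t1 - t2| <` `exclusion`; and (iv)
#' blockiness = mean(within-pre, within-on) - cross accuracy.
#'
#' @param result a [CrossTimeResult-class] with identical train and test
#'   grids.
#' @param preWindow,onWindow block windows, seconds.
#' @param exclusion band half-width around the diagonal, seconds.
#' @param decaySpan forward span of the decay fit, seconds.
#' @return list with `decay` (data.frame time/rate), `angles` (matrix,
#'   degrees), `blocks` (per-region mean accuracy and angle) and
#'   `blockiness`.
#' @export
crossTimeStatistics <- function(result, preWindow = c(-1.5, 0),
                                onWindow = c(0, 3), exclusion = 0.100,
                                decaySpan = 0.500) {
  tr <- result@trainTimes; te <- result@testTimes
  if (length(tr) != length(te) || any(abs(tr - te) > 1e-9))
    stopf("block statistics need identical train and test time grids")
  A <- result@accuracy
  # decay: slope over forward shifts within decaySpan, per 100 ms
  decay <- vapply(seq_along(tr), function(i) {
    j <- which(te >= tr[i] - 1e-9 & te <= tr[i] + decaySpan + 1e-9)
    if (length(j) < 2) return(NA_real_)
    -stats::coef(stats::lm(A[i, j] ~ I(te[j] / 0.1)))[2]
  }, 0)
  G <- crossprod(result@dv)
  angles <- acos(clip(G, -1, 1)) * 180 / pi
  diag(angles) <- 0
  in_pre <- tr >= preWindow[1] & tr < preWindow[2]
  in_on <- tr >= onWindow[1] & tr < onWindow[2]
  lag <- abs(outer(tr, te, `-`))
  band_ok <- lag >= exclusion - 1e-9
  lower <- outer(seq_along(tr), seq_along(te), `>`)
  masks <- list(
    withinPre = outer(in_pre, in_pre, `&`) & lower & band_ok,
    withinOn = outer(in_on, in_on, `&`) & lower & band_ok,
    cross = outer(in_pre, in_on, `&`) & band_ok)
  blocks <- lapply(masks, function(m) {
    if (!any(m)) stopf("a block region is empty after the diagonal exclusion")
    list(accuracy = mean(A[m]), angle = mean(angles[m]), n = sum(m))
  })
  blockiness <- mean(c(blocks$withinPre$accuracy, blocks$withinOn$accuracy)) -
    blocks$cross$accuracy
  list(decay = data.frame(time = tr, rate = decay), angles = angles,
       blocks = blocks, blockiness = blockiness)
}

#' Performance-equalized subset decoding (consistent vs exploratory)
#'
#' Decodes a variable separately from two behavioral subsets (typically
#' consistent vs exploratory trials) with the number of trials equalized to
#' the smallest count over the four trial-type combinations, the two
#' contexts and the two subsets, using repeated subsampling and
#' leave-one-out cross-validation. Timepoints where both subset decoders are
#' below the (recomputed, reduced-trial-count) chance threshold are excluded
#' from the accuracy-difference distribution.
#'
#' @param x a [SyntheticSession-class].
#' @param subsetLabels character per trial, e.g. the `labels` of
#'   [detectConsistentBlocks()] run per context.
#' @param variable decoded variable (default `"context"`).
#' @param timepoints decoding times (default: every valid timepoint).
#' @param nSubsample subsampling repetitions (default 20).
#' @param minPerContext inclusion rule: a subset needs at least this many
#'   trials in each context (default 10), else it is excluded with a
#'   warning.
#' @param chanceRuns randomized runs for the reduced-count chance level.
#' @param seed integer seed.
#' @param rates optional precomputed z-scored [RateTensor-class].
#' @return list with per-subset mean accuracy curves, the chance threshold,
#'   the retained timepoints and the accuracy-difference distribution
#'   (first subset minus second).
#' @export
equalizedSubsetDecode <- function(x, subsetLabels, variable = "context",
                                  timepoints = NULL, nSubsample = 20,
                                  minPerContext = 10, chanceRuns = 40,
                                  seed = 1, rates = NULL) {
  trials <- x@trials
  if (is.null(rates)) rates <- sessionRates(x)
  y_all <- labels_for(trials, variable)
  tax <- rates@timeAxis
  if (is.null(timepoints)) timepoints <- valid_timepoints(tax, 5)
  subsets <- unique(subsetLabels)
  keep_subset <- vapply(subsets, function(s) {
    cnt <- table(factor(trials$context[subsetLabels == s],
                        levels = c("visual", "audio")))
    all(cnt >= minPerContext)
  }, TRUE)
  if (!all(keep_subset))
    warnf("subset(s) %s excluded: fewer than %d trials in a context",
          paste(subsets[!keep_subset], collapse = ", "), minPerContext)
  subsets <- subsets[keep_subset]
  if (!length(subsets)) stopf("no subset satisfies the inclusion rule")
  cells <- expand.grid(type = unique(trial_type(trials)),
                       context = c("visual", "audio"),
                       subset = subsets, stringsAsFactors = FALSE)
  counts <- mapply(function(ty, cx, s)
    sum(trial_type(trials) == ty & trials$context == cx & subsetLabels == s),
    cells$type, cells$context, cells$subset)
  nEq <- min(counts)
  if (nEq < 1) stopf("a trial-type x context x subset cell is empty")
  accs <- with_seed(seed, {
    lapply(subsets, function(s) {
      reps <- vapply(seq_len(nSubsample), function(r) {
        idx <- unlist(lapply(unique(trial_type(trials)), function(ty)
          lapply(c("visual", "audio"), function(cx) {
            pool <- which(trial_type(trials) == ty & trials$context == cx &
                            subsetLabels == s)
            sample(pool, nEq)
          })))
        tc <- decodeTimecourse(subset_trials(rates, idx), labels = y_all[idx],
                               timepoints = timepoints, folds = "loo",
                               seed = sample.int(1e6, 1))
        tc@accuracy
      }, numeric(length(timepoints)))
      rowMeans(matrix(reps, nrow = length(timepoints)))
    })
  })
  names(accs) <- subsets
  ch <- chanceBaseline(rates, nRuns = chanceRuns, timepoints = timepoints,
                       folds = "loo", nTrials = nEq * nrow(cells) / length(subsets),
                       seed = derive_seed(seed, 9))
  retained <- if (length(subsets) == 2)
    which(accs[[1]] > ch$threshold | accs[[2]] > ch$threshold)
  else which(accs[[1]] > ch$threshold)
  diffs <- if (length(subsets) == 2) (accs[[1]] - accs[[2]])[retained] else NULL
  list(accuracy = accs, chance = ch$threshold, nEqualized = nEq,
       timepoints = timepoints, retained = retained, difference = diffs)
}

#' Residual partial correlation controlling for population size
#'
#' Correlates the residuals of least-squares fits of two per-session decoder
#' accuracies on the number of recorded units, removing the common
#' population-size dependence; equivalent to the partial correlation of the
#' two accuracies given the unit count.
#'
#' @param accA,accB per-session accuracies.
#' @param nUnits per-session unit counts.
#' @return list with `r`, `p` (two-sided), and the residuals.
#' @export
residualPartialCorrelation <- function(accA, accB, nUnits) {
  if (length(accA) < 4) stopf("need >= 4 sessions")
  if (stats::sd(nUnits) < 1e-12) {
    warnf("constant unit count; reporting the plain correlation")
    resA <- accA - mean(accA); resB <- accB - mean(accB)
  } else {
    resA <- stats::resid(stats::lm(accA ~ nUnits))
    resB <- stats::resid(stats::lm(accB ~ nUnits))
  }
  ct <- stats::cor.test(resA, resB, alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value,
       residualsA = unname(resA), residualsB = unname(resB))
}
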