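#' Run speed from raw treadmill displacement
#'
#' Speed is the magnitude of the discrete time derivative of the
#' forward/lateral displacement vector, low-pass filtered below 1 Hz with a
#' first-order Butterworth filter (single pass; a first-order low-pass
#' preserves nonnegativity), then averaged in 50-ms windows and pooled into
#' 150-ms triplets.
#'
#' @param displacement two-column matrix of cumulative forward and lateral
#'   displacement, cm.
#' @param fs sampling rate, Hz.
#' @param cutoff low-pass cutoff, Hz (default 1).
#' @param windowSec averaging window, seconds (default 0.050).
#' @param poolWindows windows pooled into the low-resolution trace
#'   (default 3, i.e. 150 ms).
#' @return list with `speed` (filtered full-rate trace, cm/s), `window`
#'   (50-ms means), `pooled` (150-ms means), `fs`, `windowSec`.
#' @export
preprocessRunspeed <- function(displacement, fs, cutoff = 1,
                               windowSec = 0.050, poolWindows = 3) {
  displacement <- as.matrix(displacement)
  if (ncol(displacement) != 2)
    stopf("displacement needs two channels (forward, lateral)")
  raw <- sqrt(diff(displacement[, 1])^2 + diff(displacement[, 2])^2) * fs
  bf <- signal::butter(1, cutoff / (fs / 2), type = "low")
  sp <- as.numeric(signal::filter(bf, raw))
  per <- max(1L, round(windowSec * fs))
  nw <- floor(length(sp) / per)
  win <- colMeans(matrix(sp[seq_len(nw * per)], per, nw))
  np <- floor(nw / poolWindows)
  pooled <- if (np > 0)
    colMeans(matrix(win[seq_len(np * poolWindows)], poolWindows, np))
  else numeric(0)
  list(speed = sp, window = win, pooled = pooled, fs = fs,
       windowSec = windowSec)
}

#' Histogram-matched subsampling of two groups
#'
#' Subsamples the larger group within each histogram bin so the per-bin
#' counts are exactly equal across the two groups; bins empty in either
#' group are dropped.
#'
#' @param values numeric values (e.g. trial run speeds).
#' @param group two-level grouping vector.
#' @param breaks histogram bin edges (default 0-100 cm/s at 5 cm/s).
#' @param seed integer seed.
#' @return integer indices of the retained elements.
#' @export
matchByHistogram <- function(values, group, breaks = seq(0, 100, by = 5),
                             seed = 1) {
  g <- unique(group)
  if (length(g) != 2) stopf("need exactly two groups")
  bin <- findInterval(values, breaks, rightmost.closed = TRUE)
  keep <- integer(0)
  with_seed(seed, {
    for (b in setdiff(unique(bin), 0)) {
      i1 <- which(bin == b & group == g[1])
      i2 <- which(bin == b & group == g[2])
      m <- min(length(i1), length(i2))
      if (m == 0) next
      keep <- c(keep, if (length(i1) > m) sample(i1, m) else i1,
                if (length(i2) > m) sample(i2, m) else i2)
    }
  })
  if (!length(keep)) stopf("no histogram bin is populated in both groups")
  sort(keep)
}

#' Locomotion-distribution-matched context decoding
#'
#' At each decoding timepoint, per-trial run speeds are averaged over
#' `poolWindows` consecutive 50-ms windows (150 ms by default), binned into
#' the 0-100 cm/s, 5 cm/s histogram, and the contexts are subsampled to
#' identical per-bin counts. Context is then decoded from the matched
#' trials, and compared with randomized control subsamplings of the same
#' per-context sizes; `nSubsample` repetitions of both are averaged. An
#' optional time shift displaces the speed stream relative to the neural
#' data.
#'
#' @inheritParams decodeTimecourse
#' @param speed trials x timepoints matrix, cm/s, on the rate tensor's bin
#'   grid.
#' @param timepoints decoding times (default: 150-ms spaced grid).
#' @param nSubsample matching repetitions (default 10).
#' @param poolWindows 50-ms windows pooled per speed estimate (default 3).
#' @param shift seconds between the speed and neural streams (default 0).
#' @param breaks speed histogram edges.
#' @return list with per-timepoint matched and control accuracies (averaged
#'   over repetitions), their difference, the per-repetition values, and
#'   the matched trial sets of the last repetition.
#' @export
locomotionMatchedDecoding <- function(x, variable = "context", speed,
                                      timepoints = NULL, nSubsample = 10,
                                      poolWindows = 3, shift = 0,
                                      breaks = seq(0, 100, by = 5),
                                      folds = 10, nBins = 5, seed = 1,
                                      rates = NULL) {
  inp <- decoding_input(x, variable, NULL, NULL, rates)
  rt <- subset_trials(inp$rates, inp$keep)
  speed <- speed[inp$keep, , drop = FALSE]
  y <- inp$labels
  tax <- rt@timeAxis
  bw <- diff(tax[1:2])
  win <- poolWindows * 5  # bins per pooled speed window
  if (is.null(timepoints)) {
    step <- win
    idx <- seq(1, length(tax) - 5 + 1, by = step)
    timepoints <- tax[idx]
  }
  matched <- control <- matrix(NA_real_, nSubsample, length(timepoints))
  sets <- vector("list", length(timepoints))
  for (ti in seq_along(timepoints)) {
    i0 <- which(abs(tax - (timepoints[ti] + shift)) < 1e-9)
    if (!length(i0)) stopf("shifted speed window outside the time axis")
    si <- i0:min(i0 + win - 1, ncol(speed))
    sp_val <- rowMeans(speed[, si, drop = FALSE])
    for (r in seq_len(nSubsample)) {
      sd_r <- derive_seed(seed, 1000 * ti + r)
      keep <- matchByHistogram(sp_val, y, breaks, seed = sd_r)
      nA <- sum(y[keep] == y[1]); nB <- length(keep) - nA
      ctrl <- with_seed(derive_seed(sd_r, 7), {
        c(sample(which(y == y[1]), nA), sample(which(y != y[1]), nB))
      })
      dec <- function(idx) {
        f <- min(folds, max(2, floor(min(table(y[idx])) / 2)))
        tc <- decodeTimecourse(subset_trials(rt, idx), labels = y[idx],
                               timepoints = timepoints[ti], nBins = nBins,
                               folds = f, seed = derive_seed(sd_r, 3))
        tc@accuracy
      }
      matched[r, ti] <- dec(keep)
      control[r, ti] <- dec(ctrl)
      if (r == nSubsample) sets[[ti]] <- keep
    }
  }
  diff_rt <- colMeans(matched) - colMeans(control)
  list(timepoints = timepoints,
       matched = colMeans(matched), control = colMeans(control),
       difference = diff_rt, meanDifference = mean(diff_rt),
       controlSd = stats::sd(as.numeric(control)),
       matchedRuns = matched, controlRuns = control, matchedSets = sets)
}

#' Recursive background subtraction of a video stream
#'
#' Per pixel, the running background is
#' `b_t = bgRate * x_t + (1 - bgRate) * b_{t-1}` (initialized at the first
#' frame) and the smoothed difference is
#' `d_t = diffRate * (x_t - b_t) + (1 - diffRate) * d_{t-1}`.
#'
#' @param frames height x width x frames array.
#' @param bgRate background update rate (default 0.3).
#' @param diffRate difference update rate (default 0.9).
#' @return array of difference frames, same dimensions.
#' @export
frameDifferenceStream <- function(frames, bgRate = 0.3, diffRate = 0.9) {
  d <- dim(frames)
  if (length(d) != 3 || d[3] < 2) stopf("need a stack of at least 2 frames")
  out <- array(0, dim = d)
  b <- frames[, , 1]
  dd <- matrix(0, d[1], d[2])
  for (t in 2:d[3]) {
    xt <- frames[, , t]
    b <- bgRate * xt + (1 - bgRate) * b
    dd <- diffRate * (xt - b) + (1 - diffRate) * dd
    out[, , t] <- dd
  }
  out
}

#' Two-stage motion PCA of difference frames
#'
#' Outer stage: the first `chunkPcs` principal components of each
#' `chunkSize`-frame chunk (mean-centered per pixel within the chunk).
#' Inner stage: the concatenated chunk-PC score series over the whole
#' session is reduced to `finalPcs` session components. The reconstruction
#' path inverts both stages.
#'
#' @param diff height x width x frames array (or frames x pixels matrix).
#' @param chunkSize frames per chunk (default 3000; shorter streams fall
#'   back to a single chunk).
#' @param chunkPcs chunk components (default 200; clipped with a warning
#'   when the chunk or pixel count is smaller).
#' @param finalPcs session components (default 40).
#' @return list of class `MotionPCA`: `scores` (frames x finalPcs), inner
#'   and per-chunk loadings/centers, chunk boundaries and frame dims.
#' @export
twoStageMotionPca <- function(diff, chunkSize = 3000, chunkPcs = 200,
                              finalPcs = 40) {
  if (length(dim(diff)) == 3) {
    d <- dim(diff)
    X <- t(matrix(diff, d[1] * d[2], d[3]))
    framedim <- d[1:2]
  } else {
    X <- diff
    framedim <- NULL
  }
  n <- nrow(X); p <- ncol(X)
  starts <- seq(1, n, by = chunkSize)
  kc <- min(chunkPcs, p, min(diff(c(starts, n + 1))))
  if (kc < chunkPcs)
    warnf("chunk PCs clipped from %d to %d (chunk/pixel limit)", chunkPcs, kc)
  chunkLoad <- chunkCenter <- vector("list", length(starts))
  C <- matrix(0, n, kc)
  for (ci in seq_along(starts)) {
    idx <- starts[ci]:min(starts[ci] + chunkSize - 1, n)
    mu <- colMeans(X[idx, , drop = FALSE])
    Xc <- sweep(X[idx, , drop = FALSE], 2, mu)
    sv <- svd(Xc, nu = kc, nv = kc)
    chunkLoad[[ci]] <- sv$v
    chunkCenter[[ci]] <- mu
    C[idx, ] <- Xc %*% sv$v
  }
  kf <- min(finalPcs, kc, n)
  if (kf < finalPcs)
    warnf("session PCs clipped from %d to %d", finalPcs, kf)
  muC <- colMeans(C)
  Cc <- sweep(C, 2, muC)
  svi <- svd(Cc, nu = kf, nv = kf)
  structure(list(scores = Cc %*% svi$v, innerLoadings = svi$v,
                 innerCenter = muC, chunkLoadings = chunkLoad,
                 chunkCenters = chunkCenter, chunkStarts = starts,
                 chunkSize = chunkSize, frameDim = framedim,
                 nFrames = n, chunkPcs = kc, finalPcs = kf),
            class = "MotionPCA")
}

#' Reconstruct frames (or chunk-PC series) from a motion PCA
#'
#' @param mp a `MotionPCA` from [twoStageMotionPca()].
#' @param nPcs session components used (default all retained).
#' @param what `"frames"` for the pixel-space reconstruction, `"chunk"` for
#'   the intermediate chunk-PC series, `"cumulative"` for the cumulative sum
#'   over frames of the pixel reconstruction (undoing a differential
#'   stream).
#' @return array (frames) or matrix (chunk series).
#' @export
reconstructMotion <- function(mp, nPcs = mp$finalPcs,
                              what = c("frames", "chunk", "cumulative")) {
  what <- match.arg(what)
  S <- mp$scores[, seq_len(nPcs), drop = FALSE]
  V <- mp$innerLoadings[, seq_len(nPcs), drop = FALSE]
  Chat <- sweep(S %*% t(V), 2, mp$innerCenter, `+`)
  if (what == "chunk") return(Chat)
  p <- length(mp$chunkCenters[[1]])
  Xhat <- matrix(0, mp$nFrames, p)
  for (ci in seq_along(mp$chunkStarts)) {
    idx <- mp$chunkStarts[ci]:min(mp$chunkStarts[ci] + mp$chunkSize - 1,
                                  mp$nFrames)
    Xhat[idx, ] <- sweep(Chat[idx, , drop = FALSE] %*% t(mp$chunkLoadings[[ci]]),
                         2, mp$chunkCenters[[ci]], `+`)
  }
  if (what == "cumulative") Xhat <- apply(Xhat, 2, cumsum)
  if (is.null(mp$frameDim)) Xhat
  else array(t(Xhat), dim = c(mp$frameDim, mp$nFrames))
}

#' Absolute motion level per frame
#'
#' Mean over principal components of the absolute component amplitudes,
#' smoothed with a 4-backward / 4-forward 9-frame moving average (edges
#' renormalized).
#'
#' @param scores frames x components matrix (e.g. `$scores` of
#'   [twoStageMotionPca()]).
#' @param smooth moving-average width in frames (default 9).
#' @return numeric vector, one nonnegative value per frame.
#' @export
absoluteMotion <- function(scores, smooth = 9) {
  scores <- as.matrix(scores)
  sm <- apply(abs(scores), 2, centered_moving_average, width = smooth)
  rowMeans(matrix(sm, nrow(scores)))
}

#' Region-of-interest motion level
#'
#' Mean absolute smoothed-difference intensity over each RoI mask, per
#' frame; with the full frame as mask this equals the global mean absolute
#' difference.
#'
#' @param diff height x width x frames difference array.
#' @param masks named list of logical height x width masks.
#' @return frames x RoI matrix.
#' @export
roiMotion <- function(diff, masks) {
  d <- dim(diff)
  out <- vapply(masks, function(m) {
    if (!any(m)) stopf("empty RoI mask")
    flat <- matrix(abs(diff), d[1] * d[2], d[3])
    colMeans(flat[as.vector(m), , drop = FALSE])
  }, numeric(d[3]))
  matrix(out, d[3], length(masks), dimnames = list(NULL, names(masks)))
}

#' Stationary-trial selection
#'
#' A trial is stationary when the fraction of its frames whose absolute
#' motion exceeds `threshold` is at most `allowedProportion`.
#'
#' @param motionByTrial trials x frames matrix of absolute motion values.
#' @param threshold motion threshold.
#' @param allowedProportion allowed fraction of over-threshold frames.
#' @return logical vector over trials.
#' @export
stationaryTrials <- function(motionByTrial, threshold, allowedProportion) {
  rowMeans(motionByTrial > threshold) <= allowedProportion
}

#' Sweep the stationarity grid
#'
#' Default grid: thresholds 0.2-2.0, allowed proportions 0.05-0.50.
#'
#' @inheritParams stationaryTrials
#' @param thresholds,proportions grid values.
#' @return data.frame with one row per grid point (`threshold`,
#'   `proportion`, `nStationary`) and the selections as a list column
#'   `trials`.
#' @export
stationarySweep <- function(motionByTrial,
                            thresholds = seq(0.2, 2.0, by = 0.2),
                            proportions = seq(0.05, 0.50, by = 0.05)) {
  grid <- expand.grid(threshold = thresholds, proportion = proportions)
  sel <- lapply(seq_len(nrow(grid)), function(i)
    stationaryTrials(motionByTrial, grid$threshold[i], grid$proportion[i]))
  grid$nStationary <- vapply(sel, sum, 0L)
  grid$trials <- sel
  grid
}

#' Motion-level-equalized context decoding
#'
#' At each decoding timepoint, trials are binned by their absolute motion
#' level; bins with fewer than `minTrials` trials in either context are
#' excluded, the remaining bins are equalized across contexts by
#' subsampling, and the decoder runs on the retained trials of each bin.
#' Accuracies are averaged over retained (timepoint, bin) cells. The
#' control repeats the procedure with motion levels shuffled across trials.
#'
#' @inheritParams decodeTimecourse
#' @param motionLevels trials x timepoints matrix of absolute motion
#'   aligned to the decoding grid (a single column is recycled).
#' @param breaks motion-level bin edges.
#' @param minTrials per-context minimum per bin (default 5).
#' @param shuffleControl also compute the level-shuffled control.
#' @return list with `accuracy`, `control`, per-cell table `cells`, and the
#'   retained (timepoint, bin) pairs.
#' @export
motionEqualizedDecoding <- function(x, variable = "context", motionLevels,
                                    breaks, timepoints = NULL, minTrials = 5,
                                    folds = 10, nBins = 5, seed = 1,
                                    shuffleControl = TRUE, rates = NULL) {
  inp <- decoding_input(x, variable, NULL, NULL, rates)
  rt <- subset_trials(inp$rates, inp$keep)
  y <- inp$labels
  tax <- rt@timeAxis
  if (is.null(timepoints)) timepoints <- valid_timepoints(tax, nBins)
  motionLevels <- as.matrix(motionLevels)[inp$keep, , drop = FALSE]
  if (ncol(motionLevels) == 1)
    motionLevels <- motionLevels[, rep(1, length(timepoints)), drop = FALSE]
  run <- function(lv, seed0) {
    cells <- NULL
    accs <- c()
    for (ti in seq_along(timepoints)) {
      bins <- findInterval(lv[, ti], breaks, rightmost.closed = TRUE)
      for (b in setdiff(unique(bins), 0)) {
        i1 <- which(bins == b & y == 1); i0 <- which(bins == b & y == 0)
        if (length(i1) < minTrials || length(i0) < minTrials) next
        m <- min(length(i1), length(i0))
        sd_c <- derive_seed(seed0, 97 * ti + b)
        idx <- with_seed(sd_c, c(sample(i1, m), sample(i0, m)))
        f <- min(folds, max(2, floor(m / 2)))
        a <- if (f >= 2 && m >= 2 * f) {
          tc <- decodeTimecourse(subset_trials(rt, idx), labels = y[idx],
                                 timepoints = timepoints[ti], nBins = nBins,
                                 folds = f, seed = derive_seed(sd_c, 5))
          tc@accuracy
        } else NA_real_
        if (!is.na(a)) {
          accs <- c(accs, a)
          cells <- rbind(cells, data.frame(timepoint = timepoints[ti],
                                           bin = b, n = m, accuracy = a))
        }
      }
    }
    list(mean = if (length(accs)) mean(accs) else
      stopf("no (timepoint, motion bin) cell retained"), cells = cells)
  }
  main <- run(motionLevels, seed)
  ctrl <- NULL
  if (shuffleControl) {
    perm <- with_seed(derive_seed(seed, 31), sample.int(nrow(motionLevels)))
    ctrl <- run(motionLevels[perm, , drop = FALSE], derive_seed(seed, 32))
  }
  list(accuracy = main$mean, control = if (!is.null(ctrl)) ctrl$mean else NA_real_,
       cells = main$cells, controlCells = if (!is.null(ctrl)) ctrl$cells)
}
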