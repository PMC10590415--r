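#' Decision vector of a decoder over a time window
#'
#' Averages the fold-averaged decoder coefficient vectors over the window's
#' timepoints (default the first 1.5 s after stimulus onset) and normalizes
#' to unit length.
#'
#' @param tc a [DecoderTimecourse-class].
#' @param window seconds, inclusive (default `c(0, 1.5)`).
#' @return unit-norm numeric vector over units, with attributes `variable`
#'   and `window`.
#' @export
decisionVector <- function(tc, window = c(0, 1.5)) {
  stopifnot(is(tc, "DecoderTimecourse"))
  sel <- tc@timeAxis >= window[1] - 1e-9 & tc@timeAxis <= window[2] + 1e-9
  if (!any(sel)) stopf("no decoder timepoints inside the window [%g, %g]",
                       window[1], window[2])
  d <- unit_norm(rowMeans(tc@dvRaw[, sel, drop = FALSE]))
  structure(d, variable = tc@variable, window = window)
}

#' Angle between two decision vectors
#'
#' `arccos(d1 . d2)` in degrees, in \[0, 180\]; optionally folded to
#' \[0, 90\].
#'
#' @param d1,d2 vectors (normalized internally; zero vectors error).
#' @param fold fold angles above 90 degrees back (default FALSE: obtuse
#'   angles are reported as such).
#' @return angle in degrees.
#' @export
dvAngle <- function(d1, d2, fold = FALSE) {
  a <- acos(clip(sum(unit_norm(d1) * unit_norm(d2)), -1, 1)) * 180 / pi
  if (fold && a > 90) 180 - a else a
}

#' Subspace projector from a DV basis
#'
#' Builds the (generally oblique) projection operator
#' `P = D (D'D)^-1 D'` onto the span of the decision vectors, and the
#' Gram-Schmidt orthonormalization `Q` of the basis in the given column
#' order, used as display coordinates (standardized units). The
#' one-dimensional case reduces to `d d' / ||d||^2`.
#'
#' @param D units x K matrix of decision vectors (or a single vector).
#' @param maxCondition error when the basis condition number exceeds this
#'   (default 1e6): near-collinear DVs make `(D'D)^-1` unstable.
#' @return a [SubspaceBasis-class].
#' @export
subspaceProjector <- function(D, maxCondition = 1e6) {
  D <- as.matrix(D)
  sv <- svd(D)$d
  cond <- if (min(sv) < .Machine$double.eps) Inf else max(sv) / min(sv)
  if (cond > maxCondition)
    stopf("rank-deficient DV basis (condition number %.3g)", cond)
  P <- D %*% solve(crossprod(D)) %*% t(D)
  Q <- qr.Q(qr(D))
  # orient Q so each display axis points along its defining DV
  s <- sign(colSums(Q * D))
  Q <- sweep(Q, 2, s + (s == 0), `*`)
  new("SubspaceBasis", D = D, P = P, Q = Q, conditionNumber = cond)
}

#' Orthonormal basis of a DV's nullspace
#'
#' The `(N-1) x N` matrix `R` with orthonormal rows all orthogonal to `d`,
#' obtained from the QR decomposition of `I - d d' / ||d||^2`; `R a` is the
#' activity with the DV direction removed.
#'
#' @param d nonzero vector over units.
#' @return `(N-1) x N` matrix with `R d = 0` and `R R' = I`.
#' @export
nullspaceProjector <- function(d) {
  d <- unit_norm(d)
  Q <- qr.Q(qr(cbind(d, diag(length(d)))))
  t(Q[, 2:length(d), drop = FALSE])
}

#' Project population activity onto a task-relevant subspace
#'
#' Projects each timepoint (`mode = "timepoint"`) or the time-average over a
#' window (`mode = "average"`) of every trial onto the subspace, reported in
#' the Gram-Schmidt display coordinates of the basis.
#'
#' @param rates a [RateTensor-class].
#' @param basis a [SubspaceBasis-class].
#' @param mode `"timepoint"` or `"average"`.
#' @param window seconds, for `mode = "average"` (default `c(0, 1.5)`).
#' @return trials x K x timepoints array (`"timepoint"`) or trials x K
#'   matrix (`"average"`).
#' @export
projectTrajectories <- function(rates, basis, mode = c("timepoint", "average"),
                                window = c(0, 1.5)) {
  mode <- match.arg(mode)
  v <- rates@values
  if (dim(v)[2] != nrow(basis@Q))
    stopf("unit axis (%d) does not match the basis (%d units)",
          dim(v)[2], nrow(basis@Q))
  Q <- basis@Q
  if (mode == "average") {
    sel <- rates@timeAxis >= window[1] - 1e-9 & rates@timeAxis <= window[2] + 1e-9
    a <- apply(v[, , sel, drop = FALSE], c(1, 2), mean)
    return(a %*% Q)
  }
  d <- dim(v)
  out <- array(0, dim = c(d[1], ncol(Q), d[3]))
  for (t in seq_len(d[3])) out[, , t] <- v[, , t] %*% Q
  out
}

#' Outer cross-validated subspace decoding
#'
#' Decoding a variable from activity projected onto its own decoder-derived
#' subspace requires an outer cross-validation: the DV (basis) is fitted on
#' outer-training trials only, outer-test activity is projected onto it, and
#' an inner stratified CV runs on the projected outer-test data; accuracies
#' are averaged over outer folds. Subspaces: `"own"` (the variable's own 1-D
#' DV), `"nullspace"` (the `(N-1)`-dimensional complement) or `"augmented"`
#' (the own DV plus the supplied extra DVs).
#'
#' @inheritParams decodeTimecourse
#' @param subspace `"own"`, `"nullspace"` or `"augmented"`.
#' @param augmentDv matrix (or vector) of additional DVs for
#'   `"augmented"`, fixed across outer folds.
#' @param outerFolds outer folds (default 2).
#' @param innerFolds inner CV folds.
#' @param dvWindow window over which the outer-train DV is averaged.
#' @param dvTimepoints training times for the outer-train decoders
#'   (defaults to `timepoints` restricted to `dvWindow`).
#' @return list with `timepoints`, `accuracy` (averaged over outer folds),
#'   `mean` accuracy, and the per-fold DVs.
#' @export
outerCvDecode <- function(x, variable = NULL, labels = NULL,
                          subspace = c("own", "nullspace", "augmented"),
                          augmentDv = NULL, outerFolds = 2, innerFolds = 10,
                          timepoints = NULL, dvWindow = c(0, 1.5),
                          dvTimepoints = NULL, nBins = 5, seed = 1,
                          rates = NULL) {
  subspace <- match.arg(subspace)
  inp <- decoding_input(x, variable, labels, NULL, rates)
  rt <- subset_trials(inp$rates, inp$keep)
  y <- inp$labels
  tax <- rt@timeAxis
  if (is.null(timepoints)) timepoints <- valid_timepoints(tax, nBins)
  if (is.null(dvTimepoints)) {
    dvTimepoints <- timepoints[timepoints >= dvWindow[1] - 1e-9 &
                                 timepoints <= dvWindow[2] + 1e-9]
    if (!length(dvTimepoints))
      dvTimepoints <- valid_timepoints(tax, nBins)
    dvTimepoints <- dvTimepoints[dvTimepoints >= dvWindow[1] - 1e-9 &
                                   dvTimepoints <= dvWindow[2] + 1e-9]
  }
  ofold <- with_seed(seed, stratified_folds(y, outerFolds))
  acc <- matrix(0, outerFolds, length(timepoints))
  dvs <- vector("list", outerFolds)
  for (k in seq_len(outerFolds)) {
    tr_idx <- ofold != k
    tc <- decodeTimecourse(subset_trials(rt, tr_idx), labels = y[tr_idx],
                           timepoints = dvTimepoints, folds = min(innerFolds,
                             max(2, floor(min(table(y[tr_idx])) / 2))),
                           seed = derive_seed(seed, 100 + k))
    d <- decisionVector(tc, dvWindow)
    dvs[[k]] <- d
    proj <- switch(subspace,
      own = matrix(d, nrow = 1),
      nullspace = nullspaceProjector(d),
      augmented = t(subspaceProjector(cbind(d, augmentDv))@Q))
    te_idx <- which(!tr_idx)
    inner <- decodeTimecourse(subset_trials(rt, te_idx), labels = y[te_idx],
                              timepoints = timepoints,
                              folds = min(innerFolds,
                                max(2, floor(min(table(y[te_idx])) / 2))),
                              seed = derive_seed(seed, 200 + k),
                              projector = proj)
    acc[k, ] <- inner@accuracy
  }
  list(timepoints = timepoints, accuracy = colMeans(acc),
       mean = mean(acc), subspace = subspace, dvs = dvs)
}

#' Context-shift profile of projected trajectories
#'
#' For each stimulus value and each supplied DV axis, the absolute
#' difference between the across-trial mean projected trajectories of the
#' two contexts at each timepoint, plus time-averaged summaries. Used to
#' show that a context switch shifts the trajectory along the context axis
#' while leaving the stimulus axis invariant.
#'
#' @param rates a [RateTensor-class].
#' @param trials the matching trial table.
#' @param axes named list of unit-norm DVs (e.g.
#'   `list(visual = dvV, context = dvC)`).
#' @param stimulusColumn trial column defining the stimulus conditions
#'   (default `"visual_stim"`).
#' @return list: `profiles[[stimulus]][[axis]]` absolute-difference time
#'   courses, `summary` data.frame of time-averaged |differences|, and the
#'   time axis. Stimuli missing in a context are skipped with a warning.
#' @export
contextShiftProfile <- function(rates, trials, axes,
                                stimulusColumn = "visual_stim") {
  v <- rates@values
  tax <- rates@timeAxis
  stims <- setdiff(unique(trials[[stimulusColumn]]), "none")
  profiles <- list()
  rows <- NULL
  for (st in stims) {
    selA <- trials[[stimulusColumn]] == st & trials$context == "visual"
    selB <- trials[[stimulusColumn]] == st & trials$context == "audio"
    if (!any(selA) || !any(selB)) {
      warnf("stimulus '%s' missing in a context; skipped", st)
      next
    }
    profiles[[st]] <- lapply(axes, function(d) {
      pA <- vapply(seq_along(tax), function(t)
        mean(v[selA, , t, drop = FALSE][, , 1] %*% d), 0)
      pB <- vapply(seq_along(tax), function(t)
        mean(v[selB, , t, drop = FALSE][, , 1] %*% d), 0)
      abs(pA - pB)
    })
    rows <- rbind(rows, data.frame(stimulus = st, axis = names(axes),
                                   meanAbsDiff = vapply(profiles[[st]], mean, 0)))
  }
  if (!length(profiles)) stopf("no stimulus present in both contexts")
  list(profiles = profiles, summary = rows, timeAxis = tax)
}
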