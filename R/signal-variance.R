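#' Signal / noise variance decomposition
#'
#' Law-of-total-variance decomposition of a scalar signal over labeled
#' conditions: total variance = noise variance (expectation over conditions
#' of the within-condition variance) + signal variance (variance over
#' conditions of the within-condition means). Population moments
#' (denominator n) are used throughout, with conditions weighted by their
#' empirical frequency, so the identity is exact.
#'
#' @param y numeric samples.
#' @param x condition labels (>= 2 distinct values, each nonempty).
#' @return list with `total`, `noise`, `signal`, `relativeSignal`.
#' @export
varianceDecomposition <- function(y, x) {
  keep <- !is.na(x)
  y <- y[keep]; x <- x[keep]
  conds <- unique(x)
  if (length(conds) < 2) stopf("signal variance needs >= 2 conditions")
  n <- length(y)
  grand <- mean(y)
  total <- mean((y - grand)^2)
  noise <- 0; signal <- 0
  for (cc in conds) {
    yc <- y[x == cc]
    w <- length(yc) / n
    noise <- noise + w * mean((yc - mean(yc))^2)
    signal <- signal + w * (mean(yc) - grand)^2
  }
  list(total = total, noise = noise, signal = signal,
       relativeSignal = if (total > 0) signal / total else NA_real_)
}

# rate tensor -> (trials*timepoints) x units matrix plus expanded labels
concat_samples <- function(rates, labels = NULL) {
  v <- if (is(rates, "RateTensor")) rates@values else rates
  d <- dim(v)
  X <- matrix(aperm(v, c(1, 3, 2)), d[1] * d[3], d[2])
  list(X = X, labels = if (is.null(labels)) NULL else rep(labels, times = d[3]))
}

#' PCA of concatenated population activity
#'
#' Concatenates the activity of all timepoints of all trials (samples =
#' trial x timepoint, features = units) and returns the orthonormal
#' principal components with non-increasing explained variances.
#'
#' @param rates a [RateTensor-class] (or trials x units x timepoints array).
#' @return list with `rotation` (units x units orthonormal), `variance`
#'   (per-PC explained variance), `center`.
#' @export
pcaConcat <- function(rates) {
  X <- concat_samples(rates)$X
  if (nrow(X) < 2) stopf("need >= 2 samples after concatenation")
  if (all(apply(X, 2, stats::sd) < 1e-12)) stopf("degenerate (constant) input")
  p <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  rot <- p$rotation
  if (ncol(rot) < ncol(X)) {   # pad rank-deficient case to a full basis
    rot <- qr.Q(qr(cbind(rot, diag(ncol(X)))))[, seq_len(ncol(X)), drop = FALSE]
  }
  list(rotation = rot, variance = c(p$sdev^2, rep(0, ncol(X) - length(p$sdev))),
       center = p$center)
}

# cumulative relative signal variance along the columns of a basis
cumulative_curve <- function(X, labels, basis, Kmax) {
  Z <- X %*% basis[, seq_len(Kmax), drop = FALSE]
  sig <- tot <- numeric(Kmax)
  for (j in seq_len(Kmax)) {
    vd <- varianceDecomposition(Z[, j], labels)
    sig[j] <- vd$signal; tot[j] <- vd$total
  }
  cumsum(sig) / cumsum(tot)
}

#' Cumulative relative signal variance over PC subspaces
#'
#' For each K the task-variable signal variance summed over the first K PCs,
#' divided by the total variance captured by the same K PCs. At K equal to
#' the full dimension this is the full-space relative signal variance,
#' invariant under orthonormal changes of basis.
#'
#' @param rates a [RateTensor-class].
#' @param labels binary trial labels (expanded over timepoints internally).
#' @param pcs result of [pcaConcat()]; computed if `NULL`.
#' @param Kmax largest subspace dimension (clipped to the unit count with a
#'   warning).
#' @return data.frame with columns `K` and `relativeSignal`.
#' @export
cumulativeSignalVariance <- function(rates, labels, pcs = NULL, Kmax = NULL) {
  cs <- concat_samples(rates, labels)
  nU <- ncol(cs$X)
  if (is.null(Kmax)) Kmax <- nU
  if (Kmax > nU) {
    warnf("Kmax %d exceeds the %d available units; clipped", Kmax, nU)
    Kmax <- nU
  }
  if (is.null(pcs)) pcs <- pcaConcat(rates)
  data.frame(K = seq_len(Kmax),
             relativeSignal = cumulative_curve(cs$X, cs$labels, pcs$rotation, Kmax))
}

#' Random-projection baseline for the signal-variance curve
#'
#' The same cumulative computation with Haar-random orthonormal bases (QR of
#' Gaussian matrices) in place of the PCs; mean and s.e.m. over projections.
#'
#' @param rates a [RateTensor-class].
#' @param labels binary trial labels.
#' @param Kmax largest subspace dimension.
#' @param nProj number of random projections (default 20).
#' @param seed integer seed.
#' @return data.frame with columns `K`, `mean`, `sem` (0 with a warning when
#'   `nProj` is 1).
#' @export
randomProjectionBaseline <- function(rates, labels, Kmax = NULL, nProj = 20,
                                     seed = 1) {
  cs <- concat_samples(rates, labels)
  nU <- ncol(cs$X)
  if (is.null(Kmax)) Kmax <- nU
  Kmax <- min(Kmax, nU)
  curves <- with_seed(seed, {
    vapply(seq_len(nProj), function(i) {
      Q <- qr.Q(qr(matrix(stats::rnorm(nU * Kmax), nU, Kmax)))
      cumulative_curve(cs$X, cs$labels, Q, Kmax)
    }, numeric(Kmax))
  })
  curves <- matrix(curves, nrow = Kmax)
  sem <- if (nProj > 1) apply(curves, 1, stats::sd) / sqrt(nProj) else {
    warnf("s.e.m. undefined for a single projection; reported as 0")
    rep(0, Kmax)
  }
  data.frame(K = seq_len(Kmax), mean = rowMeans(curves), sem = sem)
}
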