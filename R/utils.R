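# Internal helpers shared across modules. None of these are exported.

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

# Evaluate expr under a given RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  expr
}

# Deterministic substream seeds derived from one session seed; keeps every
# random component (trials, choices, spikes, speed, video) on its own stream.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + 104729 * as.numeric(k)) %% 2147483629)
}

# Class-stratified fold assignment; per-fold class ratios match the global
# ratio up to one trial.
stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    folds[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

# L2-regularized logistic regression with fixed penalty (lambda = 1/n, the
# C = 1 convention under glmnet's 1/n loss scaling); features are used as-is.
ridge_logistic <- function(X, y) {
  if (length(unique(y)) < 2L)
    stopf("ridge_logistic: training labels contain a single class")
  fit <- withCallingHandlers(
    glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                   lambda = 1 / nrow(X), standardize = FALSE),
    warning = function(w) {
      # tiny leave-one-out training sets are intrinsic to the equalized
      # subsampling schemes; glmnet's small-class advisory is expected there
      if (grepl("fewer than 8", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  list(beta = as.numeric(fit$beta), a0 = as.numeric(fit$a0))
}

predict_ridge <- function(fit, X) {
  as.numeric(stats::plogis(fit$a0 + X %*% fit$beta) > 0.5)
}

# Row-renormalized truncated (+-4 sigma) Gaussian smoothing matrix over a
# uniform time grid; smoothed counts / bin width give unbiased rate estimates
# including near trial edges (no padding).
gaussian_kernel_matrix <- function(n, bin_width, sigma) {
  lag <- outer(seq_len(n), seq_len(n), `-`) * bin_width
  W <- stats::dnorm(lag, sd = sigma)
  W[abs(lag) > 4 * sigma] <- 0
  W / rowSums(W)
}

# Binary labels (0/1) for one of the four task variables; NA where undefined.
labels_for <- function(trials, variable) {
  switch(variable,
    context = as.numeric(trials$context == "visual"),
    visual  = ifelse(trials$visual_stim == "none", NA_real_,
                     as.numeric(trials$visual_stim == "45")),
    audio   = ifelse(trials$audio_stim == "none", NA_real_,
                     as.numeric(trials$audio_stim == "5kHz")),
    choice  = as.numeric(trials$choice == "lick"),
    stopf("unknown task variable '%s'", variable))
}

# Trial-type key: congruence x expected action.
trial_type <- function(trials) {
  paste(trials$congruence, trials$expected_action, sep = ":")
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# moving average with a centered window (half back, half forward), partial
# windows at the edges renormalized
centered_moving_average <- function(x, width) {
  n <- length(x)
  back <- (width - 1L) %/% 2L
  fwd <- width - 1L - back
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - back, 1L)
  hi <- pmin(i + fwd, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
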