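#' Classify trials: congruence, expected action, outcome
#'
#' Applies the stimulus-to-action mapping (45 deg -> go, 135 deg -> no-go;
#' 5 kHz -> go, 10 kHz -> no-go) to label every multimodal trial as
#' congruent (both modalities indicate the same action) or incongruent, to
#' derive the context-expected action, and — when a `choice` column is
#' present — to assign the outcome (hit / miss / correct_rejection /
#' false_alarm).
#'
#' @param trials data.frame with columns `context` (`"visual"`/`"audio"`),
#'   `visual_stim` (`"45"`, `"135"`, `"none"`), `audio_stim` (`"5kHz"`,
#'   `"10kHz"`, `"none"`), optionally `choice` (`"lick"`/`"nolick"`).
#' @return the trial table with `congruence`, `expected_action` and (given
#'   choices) `outcome` columns filled in.
#' @export
classifyTrials <- function(trials) {
  bad <- which(!(trials$context %in% c("visual", "audio")) |
                 !(trials$visual_stim %in% c("45", "135", "none")) |
                 !(trials$audio_stim %in% c("5kHz", "10kHz", "none")))
  if (length(bad))
    stopf("unknown stimulus or context codes in rows: %s",
          paste(utils::head(bad, 20), collapse = ", "))
  vis_go <- ifelse(trials$visual_stim == "none", NA, trials$visual_stim == "45")
  aud_go <- ifelse(trials$audio_stim == "none", NA, trials$audio_stim == "5kHz")
  trials$congruence <- ifelse(is.na(vis_go) | is.na(aud_go), "unimodal",
                              ifelse(vis_go == aud_go, "congruent", "incongruent"))
  rel_go <- ifelse(trials$context == "visual", vis_go, aud_go)
  if (anyNA(rel_go))
    stopf("relevant-modality stimulus missing in rows: %s",
          paste(utils::head(which(is.na(rel_go)), 20), collapse = ", "))
  trials$expected_action <- ifelse(rel_go, "go", "nogo")
  if (!is.null(trials$choice)) {
    if (!all(trials$choice %in% c("lick", "nolick")))
      stopf("unknown choice codes")
    lick <- trials$choice == "lick"
    trials$outcome <- ifelse(rel_go,
                             ifelse(lick, "hit", "miss"),
                             ifelse(lick, "false_alarm", "correct_rejection"))
  }
  trials
}

#' Behavioral d-prime with clipped rates
#'
#' d' = z(hit rate) - z(false-alarm rate), z the standard-normal quantile,
#' with both rates clipped to \[0.01, 0.99\] before the transform so
#' |d'| <= 2 z(0.99) = 4.6527. The combined row pools go/no-go trials over
#' the whole table; with `grouping` a column name, per-group rows are added.
#'
#' @param trials classified trial table with `expected_action` and `choice`.
#' @param grouping optional column name (e.g. `"context"`).
#' @param clipRange rate clipping bounds.
#' @return data.frame with columns `group`, `nGo`, `nNogo`, `hitRate`,
#'   `faRate`, `dprime`.
#' @export
computeDprime <- function(trials, grouping = NULL, clipRange = c(0.01, 0.99)) {
  one <- function(tt, label) {
    go <- tt$expected_action == "go"
    if (nrow(tt) == 0 || !any(go) || all(go))
      stopf("group '%s' needs at least one go and one no-go trial", label)
    hit <- clip(mean(tt$choice[go] == "lick"), clipRange[1], clipRange[2])
    fa <- clip(mean(tt$choice[!go] == "lick"), clipRange[1], clipRange[2])
    data.frame(group = label, nGo = sum(go), nNogo = sum(!go),
               hitRate = hit, faRate = fa,
               dprime = stats::qnorm(hit) - stats::qnorm(fa))
  }
  out <- one(trials, "combined")
  if (!is.null(grouping)) {
    for (g in unique(trials[[grouping]]))
      out <- rbind(out, one(trials[trials[[grouping]] == g, , drop = FALSE], g))
  }
  out
}

#' Monte-Carlo d-prime distribution under random responding
#'
#' Simulates sessions in which every response is an independent lick with
#' probability `lickProb` regardless of trial type, and returns the clipped
#' d' of each session. The chance expectation is d' = 0; the upper tail
#' calibrates the expert-performance threshold.
#'
#' @param nSessions number of simulated sessions.
#' @param nGo,nNogo go / no-go trials per session.
#' @param lickProb lick probability.
#' @param seed integer seed.
#' @param clipRange rate clipping bounds.
#' @return numeric vector of d' values, one per session.
#' @export
dprimeNull <- function(nSessions, nGo = 150, nNogo = 150, lickProb = 0.5,
                       seed = 1, clipRange = c(0.01, 0.99)) {
  with_seed(seed, {
    hit <- clip(stats::rbinom(nSessions, nGo, lickProb) / nGo,
                clipRange[1], clipRange[2])
    fa <- clip(stats::rbinom(nSessions, nNogo, lickProb) / nNogo,
               clipRange[1], clipRange[2])
    stats::qnorm(hit) - stats::qnorm(fa)
  })
}

# window fractions for the four congruence x action combinations; core of
# the consistency detector, shared with the Monte-Carlo null
consistency_curves <- function(correct, type, window, alignment) {
  n <- length(correct)
  types <- c("congruent:go", "congruent:nogo", "incongruent:go", "incongruent:nogo")
  curves <- matrix(NA_real_, n, 4, dimnames = list(NULL, types))
  back <- if (alignment == "trailing") window - 1L else window %/% 2L
  fwd <- if (alignment == "trailing") 0L else window - 1L - back
  for (j in seq_along(types)) {
    sel <- type == types[j]
    cnt <- cumsum(c(0, sel))
    cor <- cumsum(c(0, sel & correct))
    i <- seq_len(n)
    lo <- pmax(i - back, 1L); hi <- pmin(i + fwd, n)
    m <- cnt[hi + 1L] - cnt[lo]
    curves[, j] <- ifelse(m > 0, (cor[hi + 1L] - cor[lo]) / m, NA_real_)
  }
  curves
}

#' Detect consistent trial blocks
#'
#' A trial is consistent when the moving-average fraction correct exceeds
#' chance (strictly > 0.5) simultaneously for all four trial-type
#' combinations (congruent/incongruent x go/no-go) within a `window`-trial
#' window; trials whose window misses a type, or that fall before the first
#' complete window (trailing alignment), are exploratory.
#'
#' @param trials classified trial table of one context, in session order,
#'   with `outcome` filled in.
#' @param window window width in trials (default 20; must be >= 4 to be able
#'   to contain all four types).
#' @param alignment `"trailing"` (window ends at the current trial) or
#'   `"centered"`.
#' @return list with `labels` (`"consistent"`/`"exploratory"` per trial) and
#'   `curves` (trials x 4 matrix of window fractions, NA when the type is
#'   absent from the window).
#' @export
detectConsistentBlocks <- function(trials, window = 20,
                                   alignment = c("trailing", "centered")) {
  alignment <- match.arg(alignment)
  if (window < 4) stopf("window must be >= 4 to contain all four trial types")
  if (length(unique(trials$context)) > 1)
    stopf("consistency is defined per context; pass the trials of one context")
  correct <- trials$outcome %in% c("hit", "correct_rejection")
  curves <- consistency_curves(correct, trial_type(trials), window, alignment)
  ok <- rowSums(curves > 0.5, na.rm = TRUE) == 4 & !apply(is.na(curves), 1, any)
  if (alignment == "trailing" && window <= nrow(trials))
    ok[seq_len(window - 1)] <- FALSE
  list(labels = ifelse(ok, "consistent", "exploratory"), curves = curves)
}

#' Monte-Carlo null for the consistency detector
#'
#' Generates random single-context sessions (trial types i.i.d. uniform over
#' the four combinations) with responses from a constant lick-rate model,
#' applies the consistency detector, and returns the cumulative tail
#' probabilities of the number of consistent trials `N` and of the longest
#' consecutive consistent run `L`.
#'
#' @param nSessions number of sessions (default 100000).
#' @param nTrials trials per session (default 70).
#' @param lickRate constant lick probability (default 0.75).
#' @param seed integer seed.
#' @param window,alignment consistency-detector parameters.
#' @param batch sessions per vectorized batch (memory knob).
#' @return list with data.frames `N` (`n`, `pGE` = P(N >= n)) and `L`
#'   (`l`, `pGE` = P(at least one run of length >= l)), plus the call
#'   parameters.
#' @export
consistencyNull <- function(nSessions = 100000, nTrials = 70, lickRate = 0.75,
                            seed = 1, window = 20, alignment = "trailing",
                            batch = 10000) {
  if (lickRate < 0 || lickRate > 1) stopf("lickRate must lie in [0, 1]")
  types <- c("congruent:go", "congruent:nogo", "incongruent:go", "incongruent:nogo")
  back <- if (alignment == "trailing") window - 1L else window %/% 2L
  fwd <- if (alignment == "trailing") 0L else window - 1L - back
  Ns <- integer(0); Ls <- integer(0)
  with_seed(seed, {
    done <- 0
    while (done < nSessions) {
      b <- min(batch, nSessions - done); done <- done + b
      type <- matrix(sample.int(4, b * nTrials, replace = TRUE), b, nTrials)
      lick <- matrix(stats::runif(b * nTrials) < lickRate, b, nTrials)
      go <- type %in% c(1, 3); dim(go) <- dim(type)
      correct <- lick == go
      ok <- matrix(TRUE, b, nTrials)
      for (j in 1:4) {
        selj <- type == j
        cnt <- matrix(0, b, nTrials + 1L)
        cor <- matrix(0, b, nTrials + 1L)
        for (t in seq_len(nTrials)) {
          cnt[, t + 1L] <- cnt[, t] + selj[, t]
          cor[, t + 1L] <- cor[, t] + (selj[, t] & correct[, t])
        }
        for (t in seq_len(nTrials)) {
          lo <- max(t - back, 1L); hi <- min(t + fwd, nTrials)
          m <- cnt[, hi + 1L] - cnt[, lo]
          frac <- (cor[, hi + 1L] - cor[, lo]) / pmax(m, 1)
          ok[, t] <- ok[, t] & m > 0 & frac > 0.5
        }
      }
      if (alignment == "trailing" && window <= nTrials)
        ok[, seq_len(window - 1L)] <- FALSE
      Ns <- c(Ns, rowSums(ok))
      run <- integer(b); best <- integer(b)
      for (t in seq_len(nTrials)) {
        run <- ifelse(ok[, t], run + 1L, 0L)
        best <- pmax(best, run)
      }
      Ls <- c(Ls, best)
    }
  })
  grid <- 0:nTrials
  list(N = data.frame(n = grid, pGE = vapply(grid, function(k) mean(Ns >= k), 0)),
       L = data.frame(l = grid, pGE = vapply(grid, function(k) mean(Ls >= k), 0)),
       nSessions = nSessions, nTrials = nTrials, lickRate = lickRate,
       window = window, alignment = alignment)
}

# per-trial lick probabilities of the candidate choice models
choice_model_prob <- function(trials, model, par) {
  go <- trials$expected_action == "go"
  switch(model,
    correct_modality = as.numeric(go),
    opposite_modality = {
      opp_go <- ifelse(trials$context == "visual",
                       trials$audio_stim == "5kHz", trials$visual_stim == "45")
      ifelse(is.na(opp_go), 0.5, as.numeric(opp_go))
    },
    unaware_rate = rep(par, nrow(trials)),
    aware_bias = ifelse(go, 1, par),
    aware_lapse = ifelse(go, 1 - par, par),
    stopf("unknown choice model '%s'", model))
}

choice_model_npar <- c(correct_modality = 0, opposite_modality = 0,
                       unaware_rate = 1, aware_bias = 1, aware_lapse = 1)

#' Fit a Bernoulli choice model
#'
#' Fits the model's single free parameter (if any) by 1-D bounded search on
#' \[0, 1\] maximizing the Bernoulli likelihood of the observed choices, with
#' predicted lick probabilities clipped to \[0.001, 0.999\]. By default the
#' model is evaluated on consistent incongruent trials (computed per context
#' with [detectConsistentBlocks()] if the table has no `consistent` column).
#'
#' @param trials classified trial table with choices.
#' @param model one of `"correct_modality"`, `"opposite_modality"`,
#'   `"unaware_rate"`, `"aware_bias"`, `"aware_lapse"`.
#' @param evalSet optional logical vector selecting the evaluation trials.
#' @param clipRange probability clipping bounds.
#' @param tol search tolerance.
#' @return list with `model`, `parameter` (NA for parameter-free models),
#'   `nParams`, `meanLL` (mean log-likelihood per evaluated trial), `n`, and
#'   `trialIds`.
#' @export
fitChoiceModel <- function(trials, model, evalSet = NULL,
                           clipRange = c(0.001, 0.999), tol = 1e-6) {
  if (is.null(evalSet)) {
    if (is.null(trials$consistent)) {
      cons <- rep(FALSE, nrow(trials))
      for (ctx in unique(trials$context)) {
        sel <- trials$context == ctx
        cons[sel] <- detectConsistentBlocks(trials[sel, , drop = FALSE])$labels ==
          "consistent"
      }
      trials$consistent <- cons
    }
    evalSet <- trials$consistent & trials$congruence == "incongruent"
  }
  if (!model %in% names(choice_model_npar))
    stopf("unknown choice model '%s'", model)
  tt <- trials[evalSet, , drop = FALSE]
  if (nrow(tt) == 0) stopf("model '%s' has no applicable trials", model)
  y <- as.numeric(tt$choice == "lick")
  mean_ll <- function(par) {
    p <- clip(choice_model_prob(tt, model, par), clipRange[1], clipRange[2])
    mean(y * log(p) + (1 - y) * log(1 - p))
  }
  if (choice_model_npar[[model]] == 0) {
    par <- NA_real_; ll <- mean_ll(NA_real_)
  } else {
    opt <- stats::optimize(mean_ll, c(0, 1), maximum = TRUE, tol = tol)
    par <- opt$maximum; ll <- opt$objective
    # the bounded search never quite reaches the boundary; snap when better
    for (b in c(0, 1)) if (mean_ll(b) >= ll) { par <- b; ll <- mean_ll(b) }
  }
  list(model = model, parameter = par, nParams = choice_model_npar[[model]],
       meanLL = ll, n = nrow(tt),
       trialIds = if (!is.null(tt$trial_id)) tt$trial_id else which(evalSet))
}

#' Rank fitted choice models by mean log-likelihood
#'
#' @param fits list of fits from [fitChoiceModel()], all evaluated on the
#'   same trial set.
#' @return data.frame ordered by descending mean log-likelihood; exact ties
#'   are broken by fewer parameters, then model name.
#' @export
compareChoiceModels <- function(fits) {
  ids <- lapply(fits, `[[`, "trialIds")
  if (length(unique(vapply(ids, function(i) paste(i, collapse = ","), ""))) > 1)
    stopf("fits were evaluated on different trial sets")
  df <- data.frame(model = vapply(fits, `[[`, "", "model"),
                   parameter = vapply(fits, `[[`, 0, "parameter"),
                   nParams = vapply(fits, `[[`, 0, "nParams"),
                   meanLL = vapply(fits, `[[`, 0, "meanLL"))
  df[order(-df$meanLL, df$nParams, df$model), , drop = FALSE]
}
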