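#' Deterministic orthonormal population directions
#'
#' Returns `k` orthonormal unit vectors over `nUnits` units, derived from a
#' QR decomposition of a seeded Gaussian matrix. Used to place ground-truth
#' modulation directions of the generator in (by default) mutually orthogonal
#' population subspaces.
#'
#' @param nUnits population size.
#' @param k number of directions (`k <= nUnits`).
#' @param seed integer seed.
#' @return a `nUnits x k` matrix with orthonormal columns.
#' @export
orthogonalDirections <- function(nUnits, k, seed = 1) {
  if (k > nUnits) stopf("cannot draw %d orthogonal directions in %d dimensions", k, nUnits)
  with_seed(seed, {
    Q <- qr.Q(qr(matrix(stats::rnorm(nUnits * k), nUnits, k)))
    # fix signs so the result does not depend on LAPACK conventions
    sweep(Q, 2, sign(Q[1, ] + (Q[1, ] == 0)), `*`)
  })
}

#' Build a synthetic-session configuration
#'
#' Defaults emulate the recorded study conditions: blocked two-context
#' sessions with a 3-s stimulus and 3-s intertrial period on a 10-ms bin
#' grid, four trial types (congruent/incongruent x go/no-go) drawn i.i.d.
#' uniformly, Poisson populations whose context/visual/audio/choice
#' modulations lie along mutually orthogonal population directions, a
#' context-aware lapse choice strategy, and a run-speed stream with
#' configurable context coupling.
#'
#' @param nTrialsPerContext multimodal trials per context block (default 120).
#' @param stimDuration,itiDuration stimulus / intertrial duration, seconds.
#' @param timeoutExtra extra intertrial seconds after misses and false alarms.
#' @param binWidth bin width, seconds (default 0.010).
#' @param nUnits population size.
#' @param baselineRates baseline rates in Hz (recycled over units).
#' @param modulation named list of modulation components (see
#'   [SessionConfig-class]); by default orthogonal context / visual / audio /
#'   choice components.
#' @param amplitudes named Hz amplitudes used when building the default
#'   modulation.
#' @param onsetRotationAngle degrees; rotation of rotating components
#'   (default the context component) at stimulus onset. 0 gives a stable
#'   code, 90 an orthogonal post-onset representation.
#' @param rotationPartner optional unit vector spanning the rotation plane;
#'   defaults to a deterministic direction orthogonal to all default
#'   components.
#' @param choiceStrategy list with `name` in `"context_aware"`,
#'   `"context_aware_bias"`, `"context_aware_lapse"`,
#'   `"context_unaware_rate"`, `"opposite_modality"` and optional `param`.
#' @param speedContextCoupling in \[0, 1\]; 0 makes the speed distribution
#'   identical across contexts, 1 applies the full `speedSpec$delta` offset.
#' @param speedSpec list: `base`, `delta`, `sd` (cm/s), `ar` (AR(1)
#'   coefficient of the bin-resolution speed trace).
#' @param videoSpec list: `make` (logical), `width`, `height`, `fps`,
#'   `dotSigma` (px), `noiseSd`.
#' @param seed master seed; every random component derives its own stream
#'   from it.
#' @return a validated [SessionConfig-class] object.
#' @export
sessionConfig <- function(nTrialsPerContext = 120,
                          stimDuration = 3, itiDuration = 3,
                          timeoutExtra = 0, binWidth = 0.010,
                          nUnits = 40, baselineRates = 7,
                          modulation = NULL,
                          amplitudes = c(context = 8, visual = 8, audio = 8, choice = 5),
                          onsetRotationAngle = 0,
                          rotationPartner = NULL,
                          choiceStrategy = list(name = "context_aware_lapse", param = 0.13),
                          speedContextCoupling = 0,
                          speedSpec = list(base = 10, delta = 5, sd = 4, ar = 0.9),
                          videoSpec = list(make = FALSE, width = 128, height = 64,
                                           fps = 20, dotSigma = 8, noiseSd = 20),
                          seed = 1) {
  if (length(nUnits) != 1 || is.na(nUnits) || nUnits < 1)
    stopf("configuration error in 'nUnits': must be a count >= 1")
  baselineRates <- rep_len(baselineRates, nUnits)
  dirs <- orthogonalDirections(nUnits, min(nUnits, 5), seed = derive_seed(seed, 101))
  if (is.null(modulation)) {
    vars <- intersect(names(amplitudes), c("context", "visual", "audio", "choice"))
    modulation <- lapply(seq_along(vars), function(i) list(
      variable = vars[i],
      direction = dirs[, min(i, ncol(dirs))],
      amplitude = unname(amplitudes[vars[i]]),
      profile = if (vars[i] == "context") "sustained" else "stimulus",
      rotate = vars[i] == "context"))
    names(modulation) <- vars
  } else {
    modulation <- lapply(modulation, function(m) {
      if (is.null(m$profile)) m$profile <- "sustained"
      if (is.null(m$rotate)) m$rotate <- FALSE
      m
    })
  }
  if (is.null(rotationPartner))
    rotationPartner <- if (ncol(dirs) >= 5) dirs[, 5] else dirs[, ncol(dirs)]
  spd <- utils::modifyList(list(base = 10, delta = 5, sd = 4, ar = 0.9), speedSpec)
  vid <- utils::modifyList(list(make = FALSE, width = 128, height = 64,
                                fps = 20, dotSigma = 8, noiseSd = 20), videoSpec)
  new("SessionConfig",
      nTrialsPerContext = nTrialsPerContext, stimDuration = stimDuration,
      itiDuration = itiDuration, timeoutExtra = timeoutExtra,
      binWidth = binWidth, nUnits = nUnits, baselineRates = baselineRates,
      modulation = modulation, onsetRotationAngle = onsetRotationAngle,
      rotationPartner = rotationPartner, choiceStrategy = choiceStrategy,
      speedContextCoupling = speedContextCoupling, speedSpec = spd,
      videoSpec = vid, seed = seed)
}

# Trial skeleton: blocked contexts, i.i.d. uniform over the four
# congruence x action combinations, stimuli derived from the go/no-go mapping
# (45 deg / 5 kHz -> go; 135 deg / 10 kHz -> no-go).
generate_trial_skeleton <- function(config) {
  n <- config@nTrialsPerContext
  with_seed(derive_seed(config@seed, 1), {
    ctx <- rep(c("visual", "audio"), each = n)
    congr <- sample(c("congruent", "incongruent"), 2 * n, replace = TRUE)
    expected <- sample(c("go", "nogo"), 2 * n, replace = TRUE)
    go_vis <- ifelse(ctx == "visual", expected == "go",
                     xor(expected == "go", congr == "incongruent"))
    go_aud <- ifelse(ctx == "audio", expected == "go",
                     xor(expected == "go", congr == "incongruent"))
    data.frame(trial_id = seq_len(2 * n),
               block_id = rep(1:2, each = n),
               context = ctx,
               visual_stim = ifelse(go_vis, "45", "135"),
               audio_stim = ifelse(go_aud, "5kHz", "10kHz"),
               stringsAsFactors = FALSE)
  })
}

#' Simulate choices under a named behavioral strategy
#'
#' One Bernoulli choice per trial. The context-aware lapse strategy licks
#' with probability `1 - lambda` in 'go' trials and `lambda` in 'no-go'
#' trials; the bias strategy licks with certainty in 'go' trials and with
#' probability `beta` in 'no-go' trials; the context-unaware strategy licks
#' with a constant rate `p`; the opposite-modality strategy responds to the
#' contextually irrelevant stimulus.
#'
#' @param trials trial table carrying `context` and the two stimulus columns
#'   (`expected_action` is derived if absent).
#' @param strategy list with `name` and optional `param`.
#' @param seed integer seed.
#' @return character vector of `"lick"` / `"nolick"`.
#' @export
generateChoices <- function(trials, strategy, seed = 1) {
  if (is.character(strategy)) strategy <- list(name = strategy)
  if (is.null(trials$expected_action))
    trials <- classifyTrials(trials)
  par <- strategy$param
  go <- trials$expected_action == "go"
  p <- switch(strategy$name,
    context_aware = as.numeric(go),
    context_aware_bias = ifelse(go, 1, par),
    context_aware_lapse = ifelse(go, 1 - par, par),
    context_unaware_rate = rep(par, nrow(trials)),
    opposite_modality = {
      opp_go <- ifelse(trials$context == "visual",
                       trials$audio_stim == "5kHz",
                       trials$visual_stim == "45")
      ifelse(is.na(opp_go), 0.5, as.numeric(opp_go))
    },
    stopf("unknown choice strategy '%s'", strategy$name))
  if (anyNA(p)) stopf("strategy '%s' needs a 'param' value", strategy$name)
  with_seed(seed, ifelse(stats::runif(nrow(trials)) < p, "lick", "nolick"))
}

# signed value of a task variable per trial (+1 / -1, NA where undefined)
variable_sign <- function(trials, variable) {
  switch(variable,
    context = ifelse(trials$context == "visual", 1, -1),
    visual = ifelse(trials$visual_stim == "none", NA_real_,
                    ifelse(trials$visual_stim == "45", 1, -1)),
    audio = ifelse(trials$audio_stim == "none", NA_real_,
                   ifelse(trials$audio_stim == "5kHz", 1, -1)),
    choice = ifelse(trials$choice == "lick", 1, -1),
    stopf("unknown task variable '%s'", variable))
}

#' Generate inhomogeneous Poisson population spikes
#'
#' Per-bin rate of unit i in a trial is
#' `baseline_i + sum_v amplitude_v * direction_v[i] * s_v(trial) * profile_v(t)`,
#' floored at 0 Hz; `s_v` is the signed value (+1/-1) of the driving task
#' variable (for `variable = "speed"`, the instantaneous run speed divided by
#' 10 cm/s). Components with `rotate = TRUE` have their direction rotated by
#' `onsetRotationAngle` within the plane spanned by the direction and the
#' configured rotation partner, from stimulus onset on. Spike times are drawn
#' uniformly within each 10-ms bin (bin-wise thinning).
#'
#' @param trials classified trial table (with choices if a choice component
#'   is configured).
#' @param config a [SessionConfig-class].
#' @param seed integer seed.
#' @param speed optional trials x timepoints speed matrix (cm/s), required by
#'   `variable = "speed"` components.
#' @return list over units of lists over trials of spike-time vectors
#'   (seconds, stimulus onset at 0).
#' @export
generatePopulationSpikes <- function(trials, config, seed = 1, speed = NULL) {
  tax <- seq(-config@itiDuration, config@stimDuration - config@binWidth,
             by = config@binWidth)
  nT <- length(tax)
  nU <- config@nUnits
  bw <- config@binWidth
  on_stim <- tax >= 0
  theta <- config@onsetRotationAngle * pi / 180
  comps <- lapply(config@modulation, function(m) {
    prof <- if (is.character(m$profile)) {
      switch(m$profile, sustained = rep(1, nT), stimulus = as.numeric(on_stim),
             stopf("unknown onset profile '%s'", m$profile))
    } else rep_len(m$profile, nT)
    dir_pre <- m$direction
    dir_post <- if (isTRUE(m$rotate) && theta > 0)
      cos(theta) * m$direction + sin(theta) * config@rotationPartner
    else m$direction
    sgn <- if (m$variable == "speed") NULL else variable_sign(trials, m$variable)
    if (m$variable == "speed" && is.null(speed))
      stopf("a 'speed' modulation component needs the speed stream")
    list(m = m, prof = prof, dir_pre = dir_pre, dir_post = dir_post, sgn = sgn)
  })
  floored <- 0; total_bins <- 0
  spikes <- rep(list(vector("list", nrow(trials))), nU)
  with_seed(derive_seed(seed, 4), {
    for (tr in seq_len(nrow(trials))) {
      lam <- matrix(config@baselineRates, nU, nT)
      for (cc in comps) {
        s_t <- if (cc$m$variable == "speed") speed[tr, ] / 10
               else rep(cc$sgn[tr], nT)
        s_t[is.na(s_t)] <- 0
        w <- cc$m$amplitude * s_t * cc$prof
        lam <- lam + cc$dir_pre %o% (w * !on_stim) + cc$dir_post %o% (w * on_stim)
      }
      floored <- floored + sum(lam < 0); total_bins <- total_bins + length(lam)
      lam[lam < 0] <- 0
      counts <- matrix(stats::rpois(nU * nT, lam * bw), nU, nT)
      for (u in seq_len(nU)) {
        tot <- sum(counts[u, ])
        spikes[[u]][[tr]] <- if (tot == 0) numeric(0) else
          sort(rep(tax, counts[u, ]) + stats::runif(tot) * bw)
      }
    }
  })
  if (floored / max(total_bins, 1) > 0.01)
    warnf("modulation amplitudes drove %.1f%% of rate bins negative; floored at 0 Hz",
          100 * floored / total_bins)
  spikes
}

#' Generate run-speed traces and optional video frames
#'
#' Speed is a nonnegative AR(1) trace per trial at bin resolution whose mean
#' is offset between contexts by `speedContextCoupling * speedSpec$delta`
#' (visual context faster); at coupling 0 the two contexts share one speed
#' distribution. Video frames (when `videoSpec$make`) show an 8-px Gaussian
#' dot on a static noise background whose horizontal displacement integrates
#' the run speed, sampled at `videoSpec$fps` as 8-bit grayscale.
#'
#' @param trials trial table.
#' @param config a [SessionConfig-class].
#' @param seed integer seed.
#' @return list with `speed` (trials x timepoints, cm/s), `speedTime`
#'   (seconds) and `frames` (height x width x frames array, 0-extent when
#'   video is off).
#' @export
generateMotionStreams <- function(trials, config, seed = 1) {
  tax <- seq(-config@itiDuration, config@stimDuration - config@binWidth,
             by = config@binWidth)
  nT <- length(tax)
  spd <- config@speedSpec
  mu <- spd$base + config@speedContextCoupling * spd$delta *
    (trials$context == "visual")
  speed <- with_seed(derive_seed(seed, 2), {
    innov_sd <- spd$sd * sqrt(1 - spd$ar^2)
    out <- matrix(0, nrow(trials), nT)
    for (tr in seq_len(nrow(trials))) {
      x <- numeric(nT)
      x[1] <- stats::rnorm(1, 0, spd$sd)
      eps <- stats::rnorm(nT - 1, 0, innov_sd)
      for (t in 2:nT) x[t] <- spd$ar * x[t - 1] + eps[t - 1]
      out[tr, ] <- pmax(0, mu[tr] + x)
    }
    out
  })
  frames <- array(0, dim = c(0, 0, 0))
  vid <- config@videoSpec
  if (isTRUE(vid$make)) {
    frames <- with_seed(derive_seed(seed, 3), {
      nf_trial <- round((config@itiDuration + config@stimDuration) * vid$fps)
      nf <- nf_trial * nrow(trials)
      bg <- matrix(clip(stats::rnorm(vid$height * vid$width, 110, vid$noiseSd),
                        0, 255), vid$height, vid$width)
      arr <- array(0, dim = c(vid$height, vid$width, nf))
      xs <- seq_len(vid$width); ys <- seq_len(vid$height)
      x_pos <- vid$width / 2
      px_per_cm <- 2
      k <- 0
      for (tr in seq_len(nrow(trials))) {
        bin_of_frame <- clip(floor((seq_len(nf_trial) - 0.5) / vid$fps /
                                     config@binWidth), 1, nT)
        for (f in seq_len(nf_trial)) {
          k <- k + 1
          x_pos <- (x_pos + speed[tr, bin_of_frame[f]] * px_per_cm / vid$fps) %%
            vid$width
          blob <- 140 * exp(-(outer((ys - vid$height / 2)^2,
                                    (xs - x_pos)^2, `+`)) /
                              (2 * vid$dotSigma^2))
          arr[, , k] <- clip(round(bg + blob), 0, 255)
        }
      }
      arr
    })
  }
  list(speed = speed, speedTime = tax, frames = frames)
}

#' Generate a complete synthetic session
#'
#' Runs the full generative pipeline deterministically from
#' `config@seed`: trial skeleton, choices under the configured strategy,
#' outcome classification and timing, run-speed (and optional video)
#' streams, and Poisson population spikes. The embedded ground truth
#' (directions, amplitudes, strategy, rotation, speed parameters) is stored
#' for downstream recovery tests.
#'
#' @param config a [SessionConfig-class] from [sessionConfig()].
#' @return a [SyntheticSession-class].
#' @examples
#' sess <- generateSession(sessionConfig(nTrialsPerContext = 10, nUnits = 5))
#' head(trialTable(sess))
#' @export
generateSession <- function(config) {
  validObject(config)
  trials <- classifyTrials(generate_trial_skeleton(config))
  trials$choice <- generateChoices(trials, config@choiceStrategy,
                                   seed = derive_seed(config@seed, 11))
  trials <- classifyTrials(trials)
  # trial timing; misses and false alarms extend the intertrial gap
  dur <- config@stimDuration + config@itiDuration +
    config@timeoutExtra * (trials$outcome %in% c("miss", "false_alarm"))
  trials$t_stim_on <- cumsum(c(0, dur[-nrow(trials)]))
  trials$t_stim_off <- trials$t_stim_on + config@stimDuration
  motion <- generateMotionStreams(trials, config, seed = config@seed)
  spikes <- generatePopulationSpikes(trials, config, seed = config@seed,
                                     speed = motion$speed)
  gt <- list(
    directions = lapply(config@modulation, `[[`, "direction"),
    amplitudes = vapply(config@modulation, `[[`, 0, "amplitude"),
    variables = vapply(config@modulation, `[[`, "", "variable"),
    onsetRotationAngle = config@onsetRotationAngle,
    rotationPartner = config@rotationPartner,
    choiceStrategy = config@choiceStrategy,
    speedContextCoupling = config@speedContextCoupling,
    speedSpec = config@speedSpec,
    seed = config@seed)
  new("SyntheticSession", trials = trials, spikes = spikes,
      speed = motion$speed, speedTime = motion$speedTime,
      frames = motion$frames, groundTruth = gt, config = config)
}

#' Bin session spikes into a counts tensor
#'
#' @param session a [SyntheticSession-class].
#' @return trials x units x timepoints array of nonnegative integer spike
#'   counts on the session's 10-ms grid.
#' @export
binSpikes <- function(session) {
  cfg <- session@config
  tax <- sessionTimeAxis(session)
  edges <- c(tax, tax[length(tax)] + cfg@binWidth)
  nTr <- nrow(session@trials); nU <- length(session@spikes); nT <- length(tax)
  counts <- array(0L, dim = c(nTr, nU, nT))
  for (u in seq_len(nU)) for (tr in seq_len(nTr)) {
    st <- session@spikes[[u]][[tr]]
    if (length(st))
      counts[tr, u, ] <- tabulate(findInterval(st, edges,
                                               rightmost.closed = TRUE), nT)
  }
  counts
}
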