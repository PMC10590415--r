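# Lazily built, cached synthetic fixtures and naive oracles shared across
# test files. Everything is generated in code at test time.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# session with strong orthogonal context/visual/audio/choice codes
orth_session <- function() fixture("orth", function() {
  cfg <- sessionConfig(nTrialsPerContext = 60, nUnits = 24, seed = 3,
                       amplitudes = c(context = 10, visual = 10,
                                      audio = 8, choice = 5))
  sess <- suppressWarnings(generateSession(cfg))
  list(session = sess, rates = sessionRates(sess))
})

# session with no task modulation at all (label-free)
null_session <- function() fixture("null", function() {
  cfg <- sessionConfig(nTrialsPerContext = 60, nUnits = 16, seed = 31,
                       amplitudes = c(context = 0, visual = 0,
                                      audio = 0, choice = 0))
  sess <- generateSession(cfg)
  list(session = sess, rates = sessionRates(sess))
})

# wrap an array into a RateTensor for direct tensor-level tests
make_rate_tensor <- function(values, timeAxis, scale = "z") {
  new("RateTensor", values = values, timeAxis = timeAxis, scale = scale,
      baselineWindow = c(-1.5, 0),
      unitsDropped = data.frame(unit = integer(0), reason = character(0)))
}

# random classified single-context trial table with random choices
random_context_trials <- function(n, seed, p_lick = 0.6) {
  set.seed(seed)
  tr <- data.frame(
    trial_id = seq_len(n), context = "visual",
    visual_stim = sample(c("45", "135"), n, replace = TRUE),
    audio_stim = sample(c("5kHz", "10kHz"), n, replace = TRUE),
    stringsAsFactors = FALSE)
  tr$choice <- ifelse(runif(n) < p_lick, "lick", "nolick")
  classifyTrials(tr)
}

# independent naive-loop re-implementation of the consistency detector
# (trailing window): the oracle against which the vectorized detector is
# checked trial-for-trial
oracle_consistency <- function(trials, window = 20) {
  n <- nrow(trials)
  correct <- trials$outcome %in% c("hit", "correct_rejection")
  type <- paste(trials$congruence, trials$expected_action, sep = ":")
  types <- c("congruent:go", "congruent:nogo",
             "incongruent:go", "incongruent:nogo")
  out <- character(n)
  for (t in seq_len(n)) {
    if (t < window) { out[t] <- "exploratory"; next }
    win <- (t - window + 1):t
    ok <- TRUE
    for (ty in types) {
      idx <- win[type[win] == ty]
      if (length(idx) == 0) { ok <- FALSE; break }
      if (mean(correct[idx]) <= 0.5) { ok <- FALSE; break }
    }
    out[t] <- if (ok) "consistent" else "exploratory"
  }
  out
}
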