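test_that("trial classification applies the stimulus-action mapping", {
  tr <- data.frame(context = c("visual", "visual", "visual", "audio"),
                   visual_stim = c("45", "45", "135", "45"),
                   audio_stim = c("10kHz", "5kHz", "10kHz", "10kHz"),
                   choice = c("lick", "lick", "nolick", "lick"),
                   stringsAsFactors = FALSE)
  out <- classifyTrials(tr)
  expect_equal(out$congruence, c("incongruent", "congruent", "congruent",
                                 "incongruent"))
  expect_equal(out$expected_action, c("go", "go", "nogo", "nogo"))
  expect_equal(out$outcome, c("hit", "hit", "correct_rejection",
                              "false_alarm"))
  tr$visual_stim[2] <- "90"
  expect_error(classifyTrials(tr), "rows: 2")
})

test_that("d-prime follows the clipped inverse-normal definition", {
  mk <- function(hit, fa, n = 100) {
    data.frame(expected_action = rep(c("go", "nogo"), each = n),
               choice = c(rep(c("lick", "nolick"), c(hit * n, n - hit * n)),
                          rep(c("lick", "nolick"), c(fa * n, n - fa * n))))
  }
  # equal hit and false-alarm rates give 0 at any level
  for (r in c(0.2, 0.5, 0.9))
    expect_equal(computeDprime(mk(r, r))$dprime, 0)
  # perfect performance saturates at 2 z(0.99)
  expect_equal(computeDprime(mk(1, 0))$dprime, 2 * qnorm(0.99),
               tolerance = 1e-10)
  # antisymmetry: swapping hit and FA rates negates d'
  expect_equal(computeDprime(mk(0.8, 0.3))$dprime,
               -computeDprime(mk(0.3, 0.8))$dprime)
  # clipping caps the magnitude always
  for (s in 1:10) {
    tr <- random_context_trials(60, seed = s)
    expect_lte(abs(computeDprime(tr)$dprime), 2 * qnorm(0.99) + 1e-12)
  }
  expect_error(computeDprime(mk(1, 0)[1:100, ]), "no-go")
})

test_that("fair-coin d-prime null is centered on zero", {
  dn <- dprimeNull(4000, nGo = 150, nNogo = 150, lickProb = 0.5, seed = 5)
  expect_lt(abs(mean(dn)), 3 * sd(dn) / sqrt(4000))
})

test_that("consistency detection matches its definition and edge rules", {
  # an all-correct session becomes consistent once the window fills
  tr <- random_context_trials(80, seed = 1)
  tr$choice <- ifelse(tr$expected_action == "go", "lick", "nolick")
  tr <- classifyTrials(tr)
  cb <- detectConsistentBlocks(tr)
  expect_true(all(cb$labels[20:80] == "consistent"))
  expect_true(all(cb$labels[1:19] == "exploratory"))
  # a window fraction of exactly 0.5 is not above chance
  tr2 <- tr
  idx <- which(popMDSA:::trial_type(tr2) == "congruent:go")
  half <- idx[seq_len(floor(length(idx) / 2))]
  tr2$choice[half] <- "nolick"  # half the congruent-go trials wrong
  tr2 <- classifyTrials(tr2)
  cb2 <- detectConsistentBlocks(tr2)
  at_half <- which(abs(cb2$curves[, "congruent:go"] - 0.5) < 1e-12)
  expect_true(all(cb2$labels[at_half] == "exploratory"))
  expect_error(detectConsistentBlocks(tr, window = 3), ">= 4")
})

test_that("consistency labels equal the naive-loop oracle", {
  for (s in 1:10) {
    tr <- random_context_trials(sample(60:90, 1), seed = 100 + s,
                                p_lick = 0.75)
    got <- detectConsistentBlocks(tr)$labels
    expect_identical(got, oracle_consistency(tr))
  }
})

test_that("consistency null has coherent tail probabilities", {
  cn <- consistencyNull(nSessions = 3000, seed = 2)
  expect_equal(cn$N$pGE[cn$N$n == 0], 1)
  expect_true(all(diff(cn$N$pGE) <= 1e-12))          # monotone in N
  expect_true(all(diff(cn$L$pGE) <= 1e-12))          # monotone in L
  expect_lte(cn$N$pGE[cn$N$n == 20], cn$N$pGE[cn$N$n == 10])
  # reproducible across seeds within 3 binomial s.e.
  cn2 <- consistencyNull(nSessions = 3000, seed = 9)
  p1 <- cn$N$pGE[cn$N$n == 10]; p2 <- cn2$N$pGE[cn2$N$n == 10]
  se <- sqrt(max(p1, 1 / 3000) * (1 - min(p1, 1 - 1 / 3000)) / 3000)
  expect_lt(abs(p1 - p2), 3 * se + 1e-9)
})

test_that("choice-model fitting recovers the boundary and ranks correctly", {
  # perfect context-aware performer: lambda at the lower bound,
  # mean LL = ln(0.999) after clipping
  tr <- random_context_trials(200, seed = 3)
  tr$choice <- ifelse(tr$expected_action == "go", "lick", "nolick")
  tr <- classifyTrials(tr)
  inc <- tr$congruence == "incongruent"
  f <- fitChoiceModel(tr, "aware_lapse", evalSet = inc)
  expect_lt(f$parameter, 1e-3)
  expect_equal(f$meanLL, log(0.999), tolerance = 1e-9)
  # correct-modality data: correct model beats the opposite-modality model
  fc <- fitChoiceModel(tr, "correct_modality", evalSet = inc)
  fo <- fitChoiceModel(tr, "opposite_modality", evalSet = inc)
  expect_gt(fc$meanLL, fo$meanLL)
  expect_error(fitChoiceModel(tr, "aware_lapse", evalSet = rep(FALSE, 200)),
               "applicable")
  expect_error(fitChoiceModel(tr, "psychic", evalSet = inc), "unknown")
})

test_that("model comparison orders by mean LL with deterministic tie-breaks", {
  tr <- random_context_trials(300, seed = 4)
  inc <- tr$congruence == "incongruent"
  f1 <- fitChoiceModel(tr, "unaware_rate", evalSet = inc)
  # single fit ranks as itself
  expect_equal(compareChoiceModels(list(f1))$model, "unaware_rate")
  # identical mean LLs: fewer parameters first, then name
  f2 <- f1; f2$model <- "aware_bias"
  f3 <- f1; f3$model <- "correct_modality"; f3$nParams <- 0
  rk <- compareChoiceModels(list(f1, f2, f3))
  expect_equal(rk$model, c("correct_modality", "aware_bias", "unaware_rate"))
  f4 <- fitChoiceModel(tr, "aware_lapse", evalSet = c(inc[-1], FALSE))
  expect_error(compareChoiceModels(list(f1, f4)), "different trial sets")
})

test_that("each generating strategy is recovered by the matching model", {
  cfg <- sessionConfig(nTrialsPerContext = 500, nUnits = 2, seed = 1)
  sk <- classifyTrials(popMDSA:::generate_trial_skeleton(cfg))
  inc <- sk$congruence == "incongruent"
  cases <- list(list(strat = list(name = "context_aware_lapse", param = 0.15),
                     model = "aware_lapse"),
                list(strat = list(name = "context_aware_bias", param = 0.25),
                     model = "aware_bias"),
                list(strat = list(name = "context_unaware_rate", param = 0.7),
                     model = "unaware_rate"),
                list(strat = list(name = "opposite_modality"),
                     model = "opposite_modality"))
  models <- c("correct_modality", "opposite_modality", "unaware_rate",
              "aware_bias", "aware_lapse")
  for (cs in cases) {
    wins <- 0
    for (s in 1:5) {
      tr <- sk
      tr$choice <- generateChoices(tr, cs$strat, seed = 50 + s)
      tr <- classifyTrials(tr)
      fits <- lapply(models, fitChoiceModel, trials = tr, evalSet = inc)
      if (compareChoiceModels(fits)$model[1] == cs$model) wins <- wins + 1
    }
    expect_gte(wins, 4)
  }
})
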