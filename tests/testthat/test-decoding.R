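test_that("feature blocks concatenate 5 bins per unit, unit-major", {
  v <- array(seq_len(4 * 2 * 10), dim = c(4, 2, 10))
  tax <- seq(0, 0.09, by = 0.01)
  rt <- make_rate_tensor(v, tax)
  F1 <- buildFeatures(rt, 0.02)
  expect_equal(dim(F1), c(4, 10))
  expect_equal(F1[1, 1:5], v[1, 1, 3:7])      # unit 1 bins
  expect_equal(F1[1, 6:10], v[1, 2, 3:7])     # then unit 2
  expect_equal(ncol(buildFeatures(v[, 1, , drop = FALSE], 0, timeAxis = tax)), 5)
  expect_error(buildFeatures(rt, 0.08), "outside")
  # constant activity gives constant features across trials
  vc <- array(2, dim = c(6, 3, 10))
  Fc <- buildFeatures(vc, 0, timeAxis = tax)
  expect_equal(max(apply(Fc, 2, sd)), 0)
})

test_that("stratified folds balance class ratios to one trial", {
  set.seed(31)
  y <- rep(0:1, c(37, 63))
  f <- popMDSA:::stratified_folds(y, 10)
  tab <- table(f, y)
  expect_true(all(abs(tab[, 1] - 3.7) < 1))
  expect_true(all(abs(tab[, 2] - 6.3) < 1))
})

test_that("a strong orthogonal code is decoded nearly perfectly", {
  fx <- orth_session()
  tp <- seq(0.25, 1.5, by = 0.25)
  tc <- decodeTimecourse(fx$session, "visual", rates = fx$rates,
                         timepoints = tp, seed = 5)
  expect_gt(mean(accuracy(tc)), 0.95)
  expect_true(all(sqrt(colSums(decisionVectors(tc)^2)) - 1 < 1e-9))
  # trial filters restrict the decoded set (correct congruent no-go trials)
  flt <- function(tr) tr$congruence == "congruent" &
    tr$expected_action == "nogo" & tr$outcome == "correct_rejection"
  tcf <- decodeTimecourse(fx$session, "context", rates = fx$rates,
                          trialFilter = flt, timepoints = 0.5, folds = 5,
                          seed = 5)
  expect_equal(tcf@nTrials, sum(flt(trialTable(fx$session))))
  expect_error(decodeTimecourse(fx$session, "visual", rates = fx$rates,
                                trialFilter = function(tr) tr$visual_stim == "45",
                                timepoints = 0.5),
               "absent")
})

test_that("label-free decoding stays within the chance band", {
  fx <- null_session()
  tp <- seq(-2, 2, by = 0.5)
  ch <- chanceBaseline(fx$rates, nRuns = 15, timepoints = c(-1, 0.5, 1.5),
                       seed = 6)
  expect_gt(ch$threshold, 0.5)
  tc <- decodeTimecourse(fx$session, "context", rates = fx$rates,
                         timepoints = tp, seed = 8)
  band <- mean(ch$runs) + 2 * sd(ch$runs)
  expect_lt(mean(accuracy(tc) > band), 0.10)
})

test_that("the chance threshold shrinks with trial count", {
  fx <- null_session()
  ch200 <- chanceBaseline(fx$rates, nRuns = 12, timepoints = c(0.5, 1.5),
                          nTrials = 120, seed = 7)
  ch50 <- chanceBaseline(fx$rates, nRuns = 12, timepoints = c(0.5, 1.5),
                         nTrials = 50, folds = 5, seed = 7)
  expect_gt(ch50$threshold, ch200$threshold)
})

test_that("cross-time diagonal tracks the time-resolved decoder", {
  fx <- orth_session()
  tp <- c(0.25, 0.55, 0.95, 1.25)
  ct <- crossTimeDecode(fx$session, "visual", rates = fx$rates,
                        trainTimes = tp, seed = 2)
  tc <- decodeTimecourse(fx$session, "visual", rates = fx$rates,
                         timepoints = tp, seed = 2)
  expect_lt(max(abs(diag(accuracy(ct)) - accuracy(tc))), 0.05)
  # gamma symmetry and zero diagonal
  st <- crossTimeStatistics(ct, preWindow = c(0.2, 0.8), onWindow = c(0.8, 1.5),
                            exclusion = 0.1)
  expect_equal(st$angles, t(st$angles))
  expect_true(all(diag(st$angles) == 0))
})

test_that("a time-invariant code yields a flat matrix and zero blockiness", {
  fx <- orth_session()  # context component is sustained and unrotated
  tt <- seq(-1.45, 2.45, by = 0.35)
  ct <- crossTimeDecode(fx$session, "context", rates = fx$rates,
                        trainTimes = tt, seed = 3)
  st <- crossTimeStatistics(ct)
  expect_lt(abs(st$blockiness), 0.05)
  expect_lt(max(accuracy(ct)) - min(accuracy(ct)), 0.25)
})

test_that("cross-time statistics follow closed forms on crafted inputs", {
  tt <- seq(-1, 1.4, by = 0.2)
  n <- length(tt)
  dv <- matrix(rep(c(1, 0), n), 2)  # identical DVs at all times
  ct <- new("CrossTimeResult", variable = "context", trainTimes = tt,
            testTimes = tt, accuracy = matrix(0.8, n, n), dv = dv,
            nTrials = 100)
  st <- crossTimeStatistics(ct, preWindow = c(-1, 0), onWindow = c(0, 1.5))
  expect_true(all(st$angles < 1e-6))
  expect_equal(st$blockiness, 0)
  expect_true(all(abs(st$decay$rate) < 1e-10, na.rm = TRUE))
  # a linear accuracy ramp has decay = -slope per 100 ms
  A <- matrix(0.9, n, n)
  for (i in seq_len(n)) A[i, ] <- 0.9 - 0.2 * pmax(tt - tt[i], 0)
  ct2 <- new("CrossTimeResult", variable = "context", trainTimes = tt,
             testTimes = tt, accuracy = A, dv = dv, nTrials = 100)
  st2 <- crossTimeStatistics(ct2, preWindow = c(-1, 0), onWindow = c(0, 1.5))
  expect_equal(unname(st2$decay$rate[2]), 0.02, tolerance = 1e-9)
})

test_that("equalized subset decoding balances cells and flags small subsets", {
  fx <- orth_session()
  tr <- trialTable(fx$session)
  set.seed(41)
  subs <- sample(c("consistent", "exploratory"), nrow(tr), replace = TRUE)
  out <- equalizedSubsetDecode(fx$session, subs, timepoints = c(0.5, 1.5),
                               nSubsample = 4, chanceRuns = 6, seed = 5,
                               rates = fx$rates)
  counts <- table(popMDSA:::trial_type(tr), tr$context, subs)
  expect_equal(out$nEqualized, min(counts))
  # both subsets carry the same signal: difference centered near zero
  expect_lt(abs(mean(out$difference)), 0.1)
  # a subset below the per-context minimum is excluded with a warning
  subs2 <- subs
  subs2[subs2 == "exploratory"] <- "consistent"
  subs2[which(tr$context == "visual")[1:3]] <- "exploratory"
  expect_warning(
    out2 <- equalizedSubsetDecode(fx$session, subs2, timepoints = 0.5,
                                  nSubsample = 2, chanceRuns = 4, seed = 5,
                                  rates = fx$rates),
    "excluded")
  expect_named(out2$accuracy, "consistent")
})

test_that("residual partial correlation equals the textbook formula", {
  set.seed(42)
  for (i in 1:20) {
    n <- 12
    nu <- sample(20:60, n, replace = TRUE)
    a <- 0.4 + 0.004 * nu + rnorm(n, sd = 0.03)
    b <- 0.45 + 0.003 * nu + rnorm(n, sd = 0.03)
    r <- residualPartialCorrelation(a, b, nu)$r
    rab <- cor(a, b); ran <- cor(a, nu); rbn <- cor(b, nu)
    closed <- (rab - ran * rbn) / sqrt((1 - ran^2) * (1 - rbn^2))
    expect_equal(r, closed, tolerance = 1e-10)
  }
  # identical inputs give r = 1; constant unit count falls back with warning
  a <- c(0.5, 0.6, 0.7, 0.65, 0.58)
  expect_equal(residualPartialCorrelation(a, a, c(10, 20, 30, 40, 50))$r, 1)
  expect_warning(r0 <- residualPartialCorrelation(a, rev(a), rep(30, 5)),
                 "constant")
  expect_equal(r0$r, cor(a, rev(a)))
  expect_error(residualPartialCorrelation(a[1:3], a[1:3], 1:3), "4 sessions")
  # accuracies driven only by unit count: residual correlation near zero
  set.seed(43)
  rs <- replicate(200, {
    nu <- sample(20:60, 10, replace = TRUE)
    a <- 0.4 + 0.005 * nu + rnorm(10, sd = 0.05)
    b <- 0.4 + 0.005 * nu + rnorm(10, sd = 0.05)
    residualPartialCorrelation(a, b, nu)$r
  })
  expect_lt(abs(mean(rs)), 3 * sd(rs) / sqrt(length(rs)))
})
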