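test_that("decision vectors are unit-norm window averages", {
  fx <- orth_session()
  tc <- decodeTimecourse(fx$session, "visual", rates = fx$rates,
                         timepoints = c(0.5, 1.0), seed = 5)
  d <- decisionVector(tc, c(0, 1.5))
  expect_equal(sqrt(sum(d^2)), 1, tolerance = 1e-10)
  # a single-timepoint window returns that (collapsed) vector, normalized
  d1 <- decisionVector(tc, c(0.5, 0.5))
  expect_equal(as.numeric(d1), popMDSA:::unit_norm(tc@dvRaw[, 1]))
  expect_error(decisionVector(tc, c(2, 3)), "window")
})

test_that("angles follow arccos of the dot product", {
  e1 <- c(1, 0, 0); e2 <- c(0, 1, 0)
  expect_equal(dvAngle(e1, e1), 0)
  expect_equal(dvAngle(e1, e2), 90)
  expect_equal(dvAngle(e1, -e1), 180)
  expect_equal(dvAngle(e1, -e1, fold = TRUE), 0)
  expect_equal(dvAngle(c(1, 1, 0), e1), 45, tolerance = 1e-10)
  expect_error(dvAngle(c(0, 0, 0), e1), "zero")
})

test_that("estimated DVs align with the analytic discriminant direction", {
  # Gaussian two-class activity with isotropic noise: the optimal direction
  # is the class-mean difference itself (LDA closed form with Sigma = I)
  set.seed(51)
  n <- 400; u <- 12
  d_true <- popMDSA:::unit_norm(rnorm(u))
  labels <- rep(0:1, each = n / 2)
  v <- array(rnorm(n * u * 10), dim = c(n, u, 10))
  for (t in 1:10) v[, , t] <- v[, , t] + outer(2 * (labels - 0.5), d_true)
  rt <- make_rate_tensor(v, seq(0, 0.09, by = 0.01))
  tc <- decodeTimecourse(rt, labels = labels, timepoints = c(0, 0.05), seed = 1)
  expect_lt(dvAngle(decisionVector(tc, c(0, 0.05)), d_true), 15)
})

test_that("subspace projectors satisfy the projector algebra", {
  set.seed(52)
  for (i in 1:30) {
    u <- sample(5:20, 1)
    K <- sample(1:3, 1)
    D <- matrix(rnorm(u * K), u, K)
    D <- apply(D, 2, popMDSA:::unit_norm)
    D <- matrix(D, u, K)
    sb <- subspaceProjector(D)
    P <- projectionOperator(sb)
    expect_lt(max(abs(P %*% P - P)), 1e-10)
    expect_lt(max(abs(P - t(P))), 1e-10)
    expect_equal(sum(diag(P)), K, tolerance = 1e-8)     # rank K
    Q <- displayBasis(sb)
    expect_lt(max(abs(crossprod(Q) - diag(K))), 1e-10)
    # nullspace identities and Pythagoras
    d <- D[, 1]
    R <- nullspaceProjector(d)
    expect_equal(dim(R), c(u - 1L, u))
    expect_lt(max(abs(R %*% d)), 1e-10)
    expect_lt(max(abs(R %*% t(R) - diag(u - 1))), 1e-10)
    a <- rnorm(u)
    expect_equal(sum(a^2), sum((R %*% a)^2) + sum(d * a)^2, tolerance = 1e-8)
    expect_lt(max(abs((diag(u) - P) %*% D)), 1e-8)       # (I - P) D = 0
  }
  # one-dimensional case reduces to d d' / ||d||^2
  d <- c(3, 4, 0)
  sb1 <- subspaceProjector(popMDSA:::unit_norm(d))
  expect_equal(projectionOperator(sb1), outer(d, d) / sum(d^2),
               tolerance = 1e-12)
  expect_error(subspaceProjector(cbind(c(1, 0), c(1, 1e-9))), "condition")
  expect_error(nullspaceProjector(c(0, 0, 0)), "zero")
})

test_that("trajectory projection is exact in-span and zero out-of-span", {
  set.seed(53)
  u <- 10
  D <- qr.Q(qr(matrix(rnorm(u * 2), u, 2)))
  sb <- subspaceProjector(D)
  # trials whose activity lies in span(D)
  coef2 <- matrix(rnorm(12 * 2), 12, 2)
  v <- array(0, dim = c(12, u, 3))
  for (t in 1:3) v[, , t] <- coef2 %*% t(D)
  rt <- make_rate_tensor(v, c(0, 0.01, 0.02))
  pr <- projectTrajectories(rt, sb, mode = "average", window = c(0, 0.02))
  recon <- pr %*% t(displayBasis(sb))
  expect_equal(recon, v[, , 1], tolerance = 1e-10)
  # orthogonal activity projects to zero
  ncol_basis <- popMDSA:::unit_norm(qr.Q(qr(cbind(D, rnorm(u))))[, 3])
  v0 <- array(rep(outer(rnorm(12), ncol_basis), 3), dim = c(12, u, 3))
  rt0 <- make_rate_tensor(v0, c(0, 0.01, 0.02))
  expect_lt(max(abs(projectTrajectories(rt0, sb, mode = "average",
                                        window = c(0, 0.02)))), 1e-10)
  # per-timepoint mode keeps the full time axis
  tr <- projectTrajectories(rt, sb)
  expect_equal(dim(tr), c(12, 2, 3))
})

test_that("context and visual clusters separate along their own axes", {
  set.seed(54)
  u <- 16; n <- 120
  dirs <- orthogonalDirections(u, 2, seed = 5)
  ctx <- rep(c(1, -1), each = n / 2)
  vis <- rep(c(1, -1), times = n / 2)
  v <- array(rnorm(n * u * 4, sd = 0.3), dim = c(n, u, 4))
  for (t in 1:4)
    v[, , t] <- v[, , t] + outer(ctx, dirs[, 1]) + outer(vis, dirs[, 2])
  rt <- make_rate_tensor(v, seq(0, 0.03, by = 0.01))
  sb <- subspaceProjector(dirs)
  pr <- projectTrajectories(rt, sb, mode = "average", window = c(0, 0.03))
  # four separated cluster means; context separates on axis 1, visual on 2
  ctx_sep <- abs(mean(pr[ctx == 1, 1]) - mean(pr[ctx == -1, 1]))
  vis_sep <- abs(mean(pr[vis == 1, 2]) - mean(pr[vis == -1, 2]))
  ctx_leak <- abs(mean(pr[ctx == 1, 2]) - mean(pr[ctx == -1, 2]))
  vis_leak <- abs(mean(pr[vis == 1, 1]) - mean(pr[vis == -1, 1]))
  expect_gt(ctx_sep, 1.5); expect_gt(vis_sep, 1.5)
  expect_lt(ctx_leak, 0.3); expect_lt(vis_leak, 0.3)
})

test_that("augmenting with an orthogonal DV does not improve decoding", {
  # independent codes: the visual subspace carries no context information,
  # so adding the visual DV to the context basis leaves accuracy unchanged
  fx <- orth_session()
  tp <- seq(0, 1.5, by = 0.5)
  dV <- decisionVector(decodeTimecourse(fx$session, "visual",
                                        rates = fx$rates, timepoints = tp,
                                        seed = 5))
  own <- outerCvDecode(fx$session, "context", rates = fx$rates,
                       subspace = "own", timepoints = tp, seed = 4)
  aug <- outerCvDecode(fx$session, "context", rates = fx$rates,
                       subspace = "augmented", augmentDv = dV,
                       timepoints = tp, seed = 4)
  expect_lt(abs(aug$mean - own$mean), 0.1)
  # and context decoding restricted to the visual DV alone is at chance
  vis_only <- decodeTimecourse(fx$session, "context", rates = fx$rates,
                               timepoints = tp, seed = 4,
                               projector = matrix(dV, nrow = 1))
  expect_lt(mean(accuracy(vis_only)), 0.62)
})

test_that("context-shift profiles isolate the context axis", {
  set.seed(55)
  u <- 10; n <- 80; tp <- 6
  dirs <- orthogonalDirections(u, 2, seed = 7)
  trials <- data.frame(
    context = rep(c("visual", "audio"), each = n / 2),
    visual_stim = rep(c("45", "135"), times = n / 2),
    stringsAsFactors = FALSE)
  shift <- 2.5
  v <- array(rnorm(n * u * tp, sd = 0.2), dim = c(n, u, tp))
  for (t in 1:tp) {
    v[, , t] <- v[, , t] +
      outer((trials$context == "visual") * shift, dirs[, 1]) +
      outer(ifelse(trials$visual_stim == "45", 1, -1), dirs[, 2])
  }
  rt <- make_rate_tensor(v, seq(0, by = 0.01, length.out = tp))
  prof <- contextShiftProfile(rt, trials,
                              axes = list(context = dirs[, 1],
                                          visual = dirs[, 2]))
  expect_length(prof$profiles[["45"]]$context, tp)
  sm <- prof$summary
  expect_lt(abs(sm$meanAbsDiff[sm$stimulus == "45" & sm$axis == "context"] -
                  shift), 0.3)
  expect_lt(sm$meanAbsDiff[sm$stimulus == "45" & sm$axis == "visual"], 0.3)
  # identical trajectories across contexts: zero everywhere
  v0 <- array(1.3, dim = c(n, u, tp))
  prof0 <- contextShiftProfile(make_rate_tensor(v0, seq(0, by = 0.01,
                                                        length.out = tp)),
                               trials, axes = list(a = dirs[, 1]))
  expect_true(all(abs(unlist(prof0$profiles)) < 1e-10))
  # stimuli missing in one context are skipped with a warning
  tr2 <- trials; tr2$visual_stim[tr2$context == "audio" &
                                   tr2$visual_stim == "135"] <- "45"
  expect_warning(contextShiftProfile(rt, tr2,
                                     axes = list(a = dirs[, 1])), "skipped")
})
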