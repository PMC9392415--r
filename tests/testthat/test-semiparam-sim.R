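test_that("Dirichlet-multinomial MLE recovers known hyperparameters", {
  set.seed(103)
  ns <- 500
  g <- c(5, 3, 2)
  P <- t(sapply(seq_len(ns), function(i) {
    x <- rgamma(3, g)
    x / sum(x)
  }))
  cnt <- t(sapply(seq_len(ns), function(i) rmultinom(1, 1000, P[i, ])[, 1]))
  dimnames(cnt) <- list(paste0("s", seq_len(ns)), paste0("t", 1:3))
  ref <- countMatrix(cnt)
  prior <- estimateDirichletPrior(ref)
  expect_true(all(abs(prior@gamma - g) / g < 0.10))
  expect_true(prior@converged)

  # ascent: the MLE log-likelihood dominates the moment initializer and a
  # coarse grid around the truth
  mom <- ZicoSeq:::.dmMomInit(cnt)
  expect_gte(prior@loglik, ZicoSeq:::.dmLoglik(mom, cnt))
  for (mult in c(0.5, 0.8, 1.25, 2))
    expect_gte(prior@loglik, ZicoSeq:::.dmLoglik(g * mult, cnt))
})

test_that("near-constant compositions yield a large fitted concentration", {
  set.seed(104)
  ns <- 200
  gBig <- c(5, 3, 2) * 1e4     # essentially fixed composition
  P <- t(sapply(seq_len(ns), function(i) {
    x <- rgamma(3, gBig)
    x / sum(x)
  }))
  cnt <- t(sapply(seq_len(ns), function(i) rmultinom(1, 1000, P[i, ])[, 1]))
  dimnames(cnt) <- list(paste0("s", seq_len(ns)), paste0("t", 1:3))
  pConst <- estimateDirichletPrior(countMatrix(cnt))

  Pv <- t(sapply(seq_len(ns), function(i) {
    x <- rgamma(3, c(5, 3, 2))
    x / sum(x)
  }))
  cntv <- t(sapply(seq_len(ns), function(i) rmultinom(1, 1000, Pv[i, ])[, 1]))
  dimnames(cntv) <- dimnames(cnt)
  pVar <- estimateDirichletPrior(countMatrix(cntv))
  expect_gt(sum(pConst@gamma), 10 * sum(pVar@gamma))
})

test_that("posterior compositions interpolate between prior and template", {
  ref <- refFixture
  m <- nTaxa(ref)
  # prior dominance: scale gamma by ~1e6 -> draws concentrate at prior mean
  big <- methods::new("DirichletPrior",
                      gamma = priorFixture@gamma / sum(priorFixture@gamma) * 1e6,
                      loglik = 0, converged = TRUE, iterations = 1L)
  pm <- big@gamma / sum(big@gamma)
  d1 <- proportions(samplePosteriorComposition(ref, big, c(1, 2, 3), seed = 1))
  expect_lt(max(abs(t(d1) - pm)), 0.01)

  # data dominance: a deep template pins the draw to its observed proportions
  deepCnt <- counts(ref)
  deepCnt[1, ] <- round(deepCnt[1, ] / sum(deepCnt[1, ]) * 1e6)
  deep <- countMatrix(deepCnt)
  d2 <- proportions(samplePosteriorComposition(deep, priorFixture, 1L, seed = 2))
  obs <- deepCnt[1, ] / sum(deepCnt[1, ])
  expect_lt(max(abs(d2[1, ] - obs)), 0.01)
  expect_true(all(d2 > 0))

  # marginal mean of repeated draws matches (C + gamma) / sum(C + gamma)
  reps <- proportions(samplePosteriorComposition(
    ref, priorFixture, rep(5L, 4000), seed = 3))
  expected <- (counts(ref)[5, ] + priorFixture@gamma) /
    sum(counts(ref)[5, ] + priorFixture@gamma)
  expect_lt(max(abs(colMeans(reps) - expected)), 0.01)
})

test_that("covariate generator hits the requested correlation structure", {
  cz <- generateCovariates(100000, R = 0.6, "continuous", seed = 11)
  expect_lt(abs(cor(cz$X, cz$Z) - 0.6), 0.01)
  expect_lt(abs(var(cz$X) - 1 / (1 - 0.36)), 0.03)

  c0 <- generateCovariates(100000, R = 0, "continuous", seed = 12)
  expect_lt(abs(cor(c0$X, c0$Z)), 0.01)

  cb <- generateCovariates(1000, R = 0.6, "binary", seed = 13)
  expect_equal(sum(cb$X), 500)          # median split -> equal groups
  expect_error(generateCovariates(10, R = 1), "R must")
})

test_that("effect injection places signals per mode and direction", {
  set.seed(21)
  P <- proportions(samplePosteriorComposition(
    refFixture, priorFixture, 1:40, seed = 31))
  X <- rep(0:1, 20)
  Z <- rnorm(40)
  m <- ncol(P)

  # null injection reproduces P * S exactly
  cfg0 <- simulationConfig(signalDensity = 0, noiseSd = 0)
  e0 <- injectEffects(P, X, Z, cfg0, seed = 1)
  expect_equal(e0$C2, P * e0$S)
  expect_false(any(e0$truth))

  # unbalanced abundant: all positive signs, all from the top quartile
  cfgU <- simulationConfig(signalDensity = 0.10, direction = "unbalanced",
                           differentialMode = "abundant")
  eU <- injectEffects(P, X, Z, cfgU, seed = 2)
  expect_equal(sum(eU$truth), round(0.1 * m))
  expect_true(all(eU$a[eU$truth] > 0))
  topQ <- which(colMeans(P) >= quantile(colMeans(P), 0.75, type = 1))
  expect_true(all(which(eU$truth) %in% topQ))
  expect_true(all(eU$a[eU$truth] >= log(2) & eU$a[eU$truth] <= log(4)))

  # balanced signs are symmetric across seeds
  signs <- unlist(lapply(1:40, function(s) {
    e <- injectEffects(P, X, Z,
                       simulationConfig(signalDensity = 0.2), seed = s)
    sign(e$a[e$truth])
  }))
  expect_lt(abs(mean(signs > 0) - 0.5), 3 * sqrt(0.25 / length(signs)))

  # quartile too small for the requested signal count
  expect_error(injectEffects(P, X, Z,
                             simulationConfig(signalDensity = 0.5,
                                              differentialMode = "rare"),
                             seed = 3),
               "quartile")
})

test_that("count generation respects depth model and mass conservation", {
  set.seed(33)
  C2 <- matrix(rgamma(10000 * 5, 2), 10000, 5)
  cfg <- simulationConfig()
  gen <- generateCounts(C2, cfg, group = rep(0L, 10000), seed = 41)
  # negative-binomial mean 10,000 (3 MC standard errors)
  se <- 10000 * sqrt(1 / 10 + 1 / 10000) / sqrt(10000)
  expect_lt(abs(mean(gen$D) - 10000), 3 * se + 5)
  expect_equal(unname(rowSums(counts(gen$counts))), gen$D)

  # fourfold depth confounding between groups
  cfg4 <- simulationConfig(depthFold = 4)
  grp <- rep(0:1, each = 2500)
  gen4 <- generateCounts(C2[1:5000, ], cfg4, group = grp, seed = 42)
  ratio <- mean(gen4$D[grp == 1]) / mean(gen4$D[grp == 0])
  expect_lt(abs(ratio - 4), 0.15)
})

test_that("simulated datasets are deterministic and honor the config", {
  s1 <- simFixture(77, nPerGroup = 20, signalDensity = 0.1)
  s2 <- simFixture(77, nPerGroup = 20, signalDensity = 0.1)
  expect_identical(counts(s1), counts(s2))
  expect_identical(s1@X, s2@X)
  expect_identical(s1@truth, s2@truth)
  expect_equal(sum(s1@truth), round(0.1 * nTaxa(refFixture)))
  expect_equal(nSamples(s1@counts), 40)
  expect_equal(unname(rowSums(counts(s1))), s1@intermediates$D)
  # compositional closure of the true compositions
  expect_equal(unname(rowSums(proportions(s1@trueCompositions))),
               rep(1, 40))

  s0 <- simFixture(78, nPerGroup = 20, signalDensity = 0)
  expect_false(any(s0@truth))

  s3 <- simFixture(79, nPerGroup = 20, signalDensity = 0.1)
  expect_false(identical(counts(s1), counts(s3)))
})

test_that("compositional effects propagate to non-differential taxa", {
  # raising one taxon's effect strictly lowers the others' expected share
  set.seed(55)
  P <- proportions(samplePosteriorComposition(
    refFixture, priorFixture, 1:30, seed = 61))
  X <- rep(1, 30)                  # everyone exposed
  Z <- rep(0, 30)
  cfg <- simulationConfig(signalDensity = 0, noiseSd = 0)
  base <- injectEffects(P, X, Z, cfg, seed = 5)
  P2base <- base$C2 / rowSums(base$C2)
  boosted <- base$C2
  boosted[, 1] <- boosted[, 1] * 4
  P2boost <- boosted / rowSums(boosted)
  expect_true(all(P2boost[, -1] < P2base[, -1]))
})

test_that("the synthetic reference matches its design contract", {
  ref <- refFixture
  expect_gte(nSamples(ref), 190)
  expect_gte(nTaxa(ref), 90)
  # mean depth close to the 10,000-read design value (negative-binomial
  # sampling noise plus the few dropped borderline taxa)
  expect_lt(abs(mean(sampleDepths(ref)) - 10000), 1000)
  # long-tailed abundance distribution: >= 3 orders of magnitude
  ma <- colMeans(counts(ref) / sampleDepths(ref))
  expect_gte(log10(max(ma) / min(ma)), 3)
  # already passes the default filter
  expect_equal(nTaxa(filterTaxa(ref)), nTaxa(ref))
  # determinism / seed sensitivity
  expect_identical(counts(syntheticReference(50, 20, seed = 3)),
                   counts(syntheticReference(50, 20, seed = 3)))
  expect_false(identical(counts(syntheticReference(50, 20, seed = 3)),
                         counts(syntheticReference(50, 20, seed = 4))))
})
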