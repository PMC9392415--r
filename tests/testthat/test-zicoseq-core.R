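test_that("ratio transform normalizes by the reference and is monotone", {
  set.seed(71)
  P <- matrix(rbeta(40, 2, 5), 8, 5)
  P <- P / rowSums(P)
  colnames(P) <- paste0("t", 1:5)
  ref <- c(2L, 4L)
  y1 <- transformRatio(P, ref, rho = 1)
  expect_equal(y1, P / rowSums(P[, ref]))
  y05 <- transformRatio(P, ref, rho = 0.5)
  expect_equal(y05, sqrt(y1))
  # ranks within a taxon are invariant to rho
  expect_equal(apply(y05, 2, rank), apply(y1, 2, rank))
  expect_error(transformRatio(P, ref, rho = 0), "rho")
})

test_that("the F statistic equals nested least-squares and ANOVA oracles", {
  set.seed(72)
  n <- 20
  X <- matrix(rnorm(n), n, 1)
  Zr <- matrix(rnorm(2 * n), n, 2)
  y <- rnorm(n)
  design <- designMatrices(X, Zr)
  # nested-RSS oracle from two explicit lm fits
  full <- lm(y ~ cbind(Zr, X))
  red <- lm(y ~ Zr)
  rssF <- sum(residuals(full)^2)
  rssR <- sum(residuals(red)^2)
  fOracle <- ((rssR - rssF) / 1) / (rssF / (n - 1 - 3))
  expect_equal(fStatistic(y, design), fOracle)

  # classical two-group one-way ANOVA
  g <- rep(0:1, each = 10)
  dA <- designMatrices(g)
  fAnova <- summary(aov(y ~ factor(g)))[[1]]$`F value`[1]
  expect_equal(fStatistic(y, dA), fAnova)

  # constant response carries no signal
  expect_equal(fStatistic(rep(3, n), dA), 0)

  # projection invariance: X + Zc leaves F unchanged
  d2 <- designMatrices(X + Zr %*% c(2, -1), Zr)
  expect_equal(fStatistic(y, d2), fStatistic(y, design))

  # perfect fit flags +Inf
  yfit <- X[, 1] * 2
  fInf <- fStatistic(yfit, designMatrices(X))
  expect_equal(unname(as.numeric(fInf)), Inf)
})

test_that("omnibus averaging is average-inside, max-outside", {
  set.seed(73)
  n <- 12
  m <- 5
  K <- 3
  draws <- lapply(1:K, function(k) {
    M <- matrix(rbeta(n * m, 2, 8), n, m,
                dimnames = list(NULL, paste0("t", 1:m)))
    M / rowSums(M)
  })
  ref <- c(1L, 3L)
  design <- designMatrices(rep(0:1, each = 6))
  grid <- c(0.25, 0.5, 0.75)
  fs <- omnibusFStatistics(draws, ref, design, grid)
  # flat triple-loop oracle
  oracle <- matrix(0, length(grid), m)
  for (r in seq_along(grid)) for (k in 1:K) {
    Y <- transformRatio(draws[[k]], ref, grid[r])
    for (j in 1:m)
      oracle[r, j] <- oracle[r, j] + fStatistic(Y[, j], design) / K
  }
  expect_equal(fs@perRho, oracle)
  expect_equal(unname(fs@omnibus), apply(oracle, 2, max))
  # max dominance over every single-rho average
  for (r in seq_along(grid))
    expect_true(all(fs@omnibus >= fs@perRho[r, ] - 1e-12))
  # K = 1, single rho reduces to the plain statistic
  f1 <- omnibusFStatistics(draws[1], ref, design, 0.5)
  Y <- transformRatio(draws[[1]], ref, 0.5)
  expect_equal(unname(f1@omnibus),
               sapply(1:m, function(j) fStatistic(Y[, j], design)))
})

test_that("Smith permutations preserve the Z-explained design part", {
  set.seed(74)
  n <- 15
  X <- matrix(rnorm(n), n, 1)
  Zr <- matrix(rnorm(n), n, 1)
  design <- designMatrices(X, Zr)
  ens <- smithPermutations(design, B = 20, seed = 5)
  Z <- design@Z
  HZ <- Z %*% solve(crossprod(Z), t(Z))
  Xhat <- HZ %*% X
  E <- X - Xhat
  for (b in c(1, 7, 20)) {
    Xb <- ens@Xperm[[b]]
    # the deviation from the shared fitted part is a permutation of the
    # original residuals (exact multiset conservation)
    expect_equal(sort(round(Xb - Xhat, 10)), sort(round(E, 10)))
    expect_equal(Xb, Xhat + E[ens@perms[, b], , drop = FALSE])
  }
  # intercept-only: X^b is a plain permutation of X's values
  d0 <- designMatrices(X)
  e0 <- smithPermutations(d0, B = 5, seed = 6)
  for (b in 1:5)
    expect_equal(sort(e0@Xperm[[b]][, 1]), sort(X[, 1]))
  # reproducibility
  e1 <- smithPermutations(d0, B = 5, seed = 6)
  expect_identical(e0@Xperm, e1@Xperm)
})

test_that("permutation p-values are add-one corrected and null-uniform", {
  Fobs <- c(10, 0)
  Fperm <- matrix(c(1, 2, 3, 0.5, 0.2, 0.1), 3, 2)
  p <- permutationPvalues(Fobs, Fperm)
  expect_equal(p[1], 1 / 4)     # larger than all B = 3 permuted values
  FobsZ <- c(0, 0)
  expect_equal(permutationPvalues(FobsZ, abs(Fperm))[1], 1)

  # null uniformity: exchangeable statistics pooled over taxa
  set.seed(75)
  n <- 30
  m <- 500
  Y <- matrix(rnorm(n * m), n, m)
  design <- designMatrices(rep(0:1, each = 15))
  ens <- smithPermutations(design, B = 99, seed = 8)
  bases <- ZicoSeq:::.projBases(design@X, design@Z)
  fob <- ZicoSeq:::.fStatMatrix(Y, bases$QZ, bases$QX, 1, 1)
  fpm <- t(sapply(ens@Xperm, function(Xb) {
    bb <- ZicoSeq:::.projBases(Xb, design@Z)
    ZicoSeq:::.fStatMatrix(Y, bb$QZ, bb$QX, 1, 1)
  }))
  pv <- permutationPvalues(fob, fpm)
  ks <- suppressWarnings(ks.test(pv, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("the permutation FDR estimator matches exhaustive enumeration", {
  # frozen small instance computed with the brute-force oracle:
  # pooled permuted values {4,2,0,6,2,0}; exceedances at cutoffs (5,3,1)
  # are (1,2,4) so q = (0.5, 0.5, 2/3) and all taxa pass at alpha = 0.8
  Fobs <- c(5, 3, 1)
  Fperm <- rbind(c(4, 2, 0), c(6, 2, 0))
  out <- permutationFdr(Fobs, Fperm, alpha = 0.8)
  expect_equal(out$qvalues, c(0.5, 0.5, 2 / 3))
  expect_equal(out$rejected, c(TRUE, TRUE, TRUE))
  expect_equal(out, bruteFdr(Fobs, Fperm, 0.8))

  # saturated null: no rejections
  sat <- permutationFdr(c(1, 1), rbind(c(5, 5), c(6, 6)), alpha = 0.05)
  expect_false(any(sat$rejected))
  expect_true(all(sat$qvalues >= 1))
  # perfect separation: everything rejected with q = 0
  sep <- permutationFdr(c(9, 8), rbind(c(1, 1), c(2, 2)), alpha = 0.05)
  expect_true(all(sep$rejected))
  expect_equal(sep$qvalues, c(0, 0))

  # equality with the independent oracle on random instances
  set.seed(76)
  for (i in 1:100) {
    m <- sample(2:10, 1)
    B <- sample(1:5, 1)
    Fobs <- round(rexp(m), 2)
    Fperm <- matrix(round(rexp(B * m), 2), B, m)
    alpha <- runif(1, 0.05, 0.9)
    expect_identical(permutationFdr(Fobs, Fperm, alpha),
                     bruteFdr(Fobs, Fperm, alpha))
  }
})

test_that("power is competitive with the TSS baseline under balanced signal", {
  ref200 <- syntheticReference(200, 200, seed = 42)
  prior200 <- estimateDirichletPrior(ref200)
  nRuns <- 15
  tprT <- tprZ <- numeric(nRuns)
  for (r in seq_len(nRuns)) {
    sim <- simulateDataset(ref200, prior200,
                           simulationConfig(nPerGroup = 50,
                                            signalDensity = 0.1,
                                            seed = 7000 + r))
    cm <- filterTaxa(sim@counts)
    truth <- sim@truth[match(taxonNames(cm), taxonNames(sim@counts))]
    rejT <- bhAdjust(wilcoxonDaa(cm, sim@X, "tss")) <= 0.05
    res <- runZicoSeq(cm, sim@X, B = 99, K = 10, seed = 8000 + r,
                      filter = FALSE)
    tprT[r] <- evaluateFdpTpr(rejT, truth)[["TPR"]]
    tprZ[r] <- evaluateFdpTpr(res@rejected, truth)[["TPR"]]
  }
  expect_gte(mean(tprZ), mean(tprT) - 0.05)
})

test_that("full runs are deterministic and expose a coherent result", {
  sim <- simFixture(8201, nPerGroup = 25, signalDensity = 0.1)
  cm <- filterTaxa(sim@counts)
  r1 <- runZicoSeq(cm, sim@X, B = 49, K = 5, seed = 31, filter = FALSE)
  r2 <- runZicoSeq(cm, sim@X, B = 49, K = 5, seed = 31, filter = FALSE)
  expect_identical(r1@statistics, r2@statistics)
  expect_identical(r1@pvalues, r2@pvalues)
  expect_identical(r1@qvalues, r2@qvalues)
  expect_identical(r1@rejected, r2@rejected)
  expect_identical(r1@reference@taxonIndices, r2@reference@taxonIndices)

  df <- as.data.frame(r1)
  expect_equal(nrow(df), nTaxa(cm))
  expect_true(all(df$F_omnibus >= 0))
  expect_true(all(df$p_perm > 0 & df$p_perm <= 1))
  expect_true(all(df$q_perm >= 0 & df$q_perm <= 1))
  expect_equal(sum(df$in_reference), length(r1@reference@taxonIndices))

  # covariate adjustment runs and respects the projection structure
  Zc <- rnorm(nSamples(cm))
  rz <- runZicoSeq(cm, sim@X, Z = Zc, B = 49, K = 5, seed = 31,
                   filter = FALSE)
  expect_length(rz@statistics, nTaxa(cm))
})
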