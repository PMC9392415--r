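# Shared fixtures, built once per test run.

# tiny deterministic count matrix
tinyCounts <- function() {
  countMatrix(matrix(c(1, 2, 3, 4, 5, 6), 2, 3, byrow = TRUE,
                     dimnames = list(c("s1", "s2"), c("t1", "t2", "t3"))))
}

# synthetic reference + Dirichlet prior reused across simulation tests
refFixture <- syntheticReference(200, 100, seed = 42)
priorFixture <- estimateDirichletPrior(refFixture)

# simulate one dataset under the shared reference
simFixture <- function(seed, ...) {
  simulateDataset(refFixture, priorFixture,
                  simulationConfig(seed = seed, ...))
}

# brute-force permutation-FDR oracle: explicit loops over sorted cutoffs
# and all (taxon, permutation) pairs
bruteFdr <- function(Fobs, Fperm, alpha) {
  m <- length(Fobs)
  B <- nrow(Fperm)
  ord <- order(-Fobs, seq_len(m))
  q <- numeric(m)
  for (j in seq_len(m)) {
    cnt <- 0
    for (k in seq_len(m)) for (b in seq_len(B))
      if (Fperm[b, k] >= Fobs[ord[j]]) cnt <- cnt + 1
    q[j] <- min(cnt / B / j, 1)
  }
  J <- 0
  for (j in seq_len(m)) if (q[j] <= alpha) J <- j
  rejected <- logical(m)
  if (J > 0) rejected[ord[seq_len(J)]] <- TRUE
  qv <- numeric(m)
  qv[ord] <- q
  list(qvalues = qv, rejected = rejected)
}
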