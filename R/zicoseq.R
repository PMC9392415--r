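# The core test: power-transformed reference-ratio responses, omnibus F
# statistics averaged over posterior draws, Smith permutation, and
# permutation-based FDR control with iterative reference refinement.

#' Build design matrices for testing
#'
#' @param X covariate(s) of interest: vector or n x p matrix.
#' @param Z adjustment covariates (vector or matrix) or NULL; an intercept
#'   column is always prepended.
#' @return a \code{\link{DesignMatrices}}.
#' @export
designMatrices <- function(X, Z = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  Zfull <- if (is.null(Z)) matrix(1, n, 1L) else cbind(1, as.matrix(Z))
  colnames(Zfull) <- c("(Intercept)",
                       if (ncol(Zfull) > 1L)
                         paste0("Z", seq_len(ncol(Zfull) - 1L)))
  methods::new("DesignMatrices", X = X, Z = Zfull)
}

# orthonormal bases: QZ spans col(Z); QX spans the part of col(X) orthogonal
# to col(Z).  H_Z = QZ QZ', H_{X,Z} = H_Z + QX QX'.
.projBases <- function(X, Z) {
  qrZ <- qr(Z)
  QZ <- qr.Q(qrZ)[, seq_len(qrZ$rank), drop = FALSE]
  Xres <- X - QZ %*% crossprod(QZ, X)
  qrX <- qr(Xres)
  QX <- qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE]
  list(QZ = QZ, QX = QX)
}

#' Power-transformed reference-ratio responses
#'
#' Divides each proportion by the sample's cumulative reference proportion
#' and raises the ratio to the power rho: \code{y_ij = (mu_ij /
#' mu_i^C)^rho}.  With \code{rho = 1} the raw ratios are returned; small
#' rho approaches a log relationship while down-weighting rare taxa less
#' aggressively than the log.
#'
#' @param draw samples x taxa matrix of (posterior) proportions, strictly
#'   positive.
#' @param ref a \code{\link{ReferenceSet}} or integer index vector.
#' @param rho power-transform exponent in (0, 1].
#' @return the transformed response matrix.
#' @export
transformRatio <- function(draw, ref, rho = 0.5) {
  if (rho <= 0 || rho > 1)
    stop("rho must lie in (0, 1]; use a small rho to approximate the log",
         call. = FALSE)
  if (is(ref, "ReferenceSet")) ref <- ref@taxonIndices
  if (is(draw, "ProportionMatrix")) draw <- proportions(draw)
  muC <- rowSums(draw[, ref, drop = FALSE])
  if (any(muC <= 0))
    stop("cumulative reference proportion must be positive", call. = FALSE)
  (draw / muC)^rho
}

#' F statistic through projections
#'
#' The nested-model F statistic
#' \code{[y'(H_XZ - H_Z)y / p] / [y'(I - H_XZ)y / (n - p - q)]}, computed
#' via orthonormal bases from QR decompositions (no matrix inversion).
#' A vanishing residual denominator yields +Inf with attribute
#' \code{perfectFit}.
#'
#' @param y response vector (length n).
#' @param design a \code{\link{DesignMatrices}}.
#' @return the F statistic (non-negative scalar).
#' @export
fStatistic <- function(y, design) {
  stopifnot(is(design, "DesignMatrices"))
  bases <- .projBases(design@X, design@Z)
  n <- length(y)
  p <- ncol(design@X)
  q <- ncol(design@Z)
  a <- crossprod(bases$QX, y)
  z <- crossprod(bases$QZ, y)
  num <- sum(a^2) / p
  den <- (sum(y^2) - sum(z^2) - sum(a^2)) / (n - p - q)
  tot <- sum(y^2)
  if (num <= 1e-12 * tot) return(0)     # no signal (constant/centered y)
  if (den <= max(1e-12 * tot, 0)) {
    out <- Inf
    attr(out, "perfectFit") <- TRUE
    return(out)
  }
  num / den
}

# F statistics for all columns of Y under precomputed bases; returns a
# vector of length m.  Infs where the residual vanishes.
.fStatMatrix <- function(Y, QZ, QX, p, q) {
  n <- nrow(Y)
  A <- crossprod(QX, Y)
  Zc <- crossprod(QZ, Y)
  sA <- colSums(A^2)
  num <- sA / p
  den <- (colSums(Y^2) - colSums(Zc^2) - sA) / (n - p - q)
  tot <- colSums(Y^2)
  bad <- den <= pmax(1e-12 * tot, 0)
  f <- num / den
  f[bad] <- Inf
  f[sA <= 1e-12 * tot] <- 0
  f
}

#' Omnibus F statistics averaged over posterior draws
#'
#' For each exponent in \code{rhoGrid}, computes the per-taxon F statistic
#' on every posterior draw, averages over the K draws, and finally takes
#' the maximum across exponents (average inside, max outside).
#'
#' @param draws a \code{\link{PosteriorDraws}} (or list of proportion
#'   matrices).
#' @param ref a \code{\link{ReferenceSet}} or index vector.
#' @param design a \code{\link{DesignMatrices}}.
#' @param rhoGrid exponents of the power transform; default 0.5.
#' @return an \code{\link{FStatistics}}.
#' @export
omnibusFStatistics <- function(draws, ref, design, rhoGrid = 0.5) {
  if (is(draws, "PosteriorDraws")) draws <- draws@draws
  stopifnot(length(draws) >= 1, length(rhoGrid) >= 1)
  bases <- .projBases(design@X, design@Z)
  p <- ncol(design@X); q <- ncol(design@Z)
  m <- ncol(draws[[1L]])
  perRho <- matrix(0, length(rhoGrid), m)
  for (r in seq_along(rhoGrid)) {
    acc <- numeric(m)
    for (k in seq_along(draws)) {
      Y <- transformRatio(draws[[k]], ref, rhoGrid[r])
      acc <- acc + .fStatMatrix(Y, bases$QZ, bases$QX, p, q)
    }
    perRho[r, ] <- acc / length(draws)
  }
  omnibus <- apply(perRho, 2L, max)
  names(omnibus) <- colnames(draws[[1L]])
  methods::new("FStatistics", perRho = perRho, omnibus = omnibus,
               rhoGrid = rhoGrid)
}

#' Smith permutations of the covariate of interest
#'
#' Regresses X on Z, permutes the residual rows jointly across X's
#' columns, and adds the permuted residuals back to the fitted values:
#' \code{X^b = Xhat + E^b}.  Every permuted design shares the fitted part
#' Xhat, and its deviation from Xhat is an exact permutation of the
#' original residuals; with an intercept-only Z the construction reduces
#' to a plain permutation of X's values.
#'
#' @param design a \code{\link{DesignMatrices}}.
#' @param B number of permutations (>= 1).
#' @param seed integer seed.
#' @return a \code{\link{PermutationEnsemble}}.
#' @export
smithPermutations <- function(design, B, seed = 1L) {
  stopifnot(is(design, "DesignMatrices"), B >= 1)
  X <- design@X
  n <- nrow(X)
  QZ <- .projBases(X, design@Z)$QZ
  Xhat <- QZ %*% crossprod(QZ, X)
  E <- X - Xhat
  set.seed(seed)
  perms <- replicate(B, sample.int(n))
  Xperm <- lapply(seq_len(B), function(b) Xhat + E[perms[, b], , drop = FALSE])
  methods::new("PermutationEnsemble", B = as.integer(B), perms = perms,
               Xperm = Xperm)
}

# Observed and permuted omnibus statistics in one pass.  The expensive
# inner product is batched: with a single covariate column the extra
# orthonormal basis of every permuted design is one unit vector, so all
# B + 1 designs reduce to one crossprod per draw and exponent.
.omnibusBatch <- function(drawList, refIdx, design, ens, rhoGrid) {
  X <- design@X; Z <- design@Z
  n <- nrow(X); p <- ncol(X); q <- ncol(Z)
  B <- ens@B
  bases <- .projBases(X, Z)
  QZ <- bases$QZ
  m <- ncol(drawList[[1L]])
  K <- length(drawList)
  fastPath <- p == 1L && ncol(bases$QX) == 1L
  if (fastPath) {
    U <- matrix(0, n, B + 1L)
    U[, 1L] <- bases$QX
    ok <- TRUE
    for (b in seq_len(B)) {
      v <- ens@Xperm[[b]]
      v <- v - QZ %*% crossprod(QZ, v)
      nv <- sqrt(sum(v^2))
      if (nv < 1e-12) { ok <- FALSE; break }
      U[, b + 1L] <- v / nv
    }
    fastPath <- ok
  }
  dfDen <- n - p - q
  accObs <- matrix(0, length(rhoGrid), m)
  accPerm <- array(0, dim = c(length(rhoGrid), B, m))
  for (k in seq_len(K)) {
    ratios <- drawList[[k]] /
      rowSums(drawList[[k]][, refIdx, drop = FALSE])
    for (r in seq_along(rhoGrid)) {
      Y <- ratios^rhoGrid[r]
      sYY <- colSums(Y^2)
      sZ <- colSums(crossprod(QZ, Y)^2)
      resid0 <- sYY - sZ
      if (fastPath) {
        A2 <- crossprod(U, Y)^2              # (B+1) x m
        num <- A2
        den <- (rep(1, B + 1L) %o% resid0 - A2) / dfDen
        f <- num / den
        f[den <= 1e-12 * (rep(1, B + 1L) %o% sYY)] <- Inf
        accObs[r, ] <- accObs[r, ] + f[1L, ]
        accPerm[r, , ] <- accPerm[r, , ] + f[-1L, , drop = FALSE]
      } else {
        accObs[r, ] <- accObs[r, ] +
          .fStatMatrix(Y, QZ, bases$QX, p, q)
        for (b in seq_len(B)) {
          bb <- .projBases(ens@Xperm[[b]], Z)
          accPerm[r, b, ] <- accPerm[r, b, ] +
            .fStatMatrix(Y, bb$QZ, bb$QX, p, q)
        }
      }
    }
  }
  accObs <- accObs / K
  accPerm <- accPerm / K
  obs <- apply(accObs, 2L, max)
  perm <- apply(accPerm, c(2L, 3L), max)     # B x m
  list(obs = obs, perm = perm)
}

#' Per-taxon permutation p-values
#'
#' Add-one corrected: \code{p_j = (1 + #\{b: F^b_j >= F_j\}) / (B + 1)}.
#'
#' @param Fobs per-taxon observed statistics.
#' @param Fperm B x m matrix of permuted statistics.
#' @return per-taxon p-values in (0, 1].
#' @export
permutationPvalues <- function(Fobs, Fperm) {
  stopifnot(ncol(Fperm) == length(Fobs))
  B <- nrow(Fperm)
  exceed <- colSums(Fperm >= rep(Fobs, each = B))
  (1 + exceed) / (B + 1)
}

#' Permutation-based FDR estimates and rejection set
#'
#' Sorts the observed statistics in descending order (ties broken by taxon
#' index) and estimates, for the cutoff at sorted position j,
#' \code{q_(j) = [#\{(k, b): F^b_k >= F_(j)\} / B] / j}, capped at one.
#' Rejects the sorted positions 1..J where J is the largest j with
#' \code{q_(j) <= alpha} (none when no position qualifies); this argmax
#' rule is step-up, so a later position with a small estimate rescues
#' everything before it.
#'
#' @param Fobs per-taxon observed statistics.
#' @param Fperm B x m matrix of permuted statistics.
#' @param alpha target FDR level in (0, 1); default 0.05.
#' @return list with \code{qvalues} (original taxon order) and the logical
#'   \code{rejected} vector.
#' @export
permutationFdr <- function(Fobs, Fperm, alpha = 0.05) {
  stopifnot(ncol(Fperm) == length(Fobs), alpha > 0, alpha < 1)
  m <- length(Fobs)
  B <- nrow(Fperm)
  ord <- order(-Fobs, seq_len(m))           # descending, stable
  cuts <- Fobs[ord]
  permVec <- as.vector(Fperm)
  exceed <- vapply(cuts, function(cc) sum(permVec >= cc), numeric(1L))
  qtilde <- pmin(exceed / B / seq_len(m), 1)
  J <- if (any(qtilde <= alpha)) max(which(qtilde <= alpha)) else 0L
  rejected <- logical(m)
  if (J > 0) rejected[ord[seq_len(J)]] <- TRUE
  qvalues <- numeric(m)
  qvalues[ord] <- qtilde
  list(qvalues = qvalues, rejected = rejected)
}

#' Run the full differential abundance test
#'
#' Pipeline: filter taxa, fit the empirical-Bayes beta mixture prior, draw
#' K posterior proportion samples, select the reference taxa from pairwise
#' log-ratio residual variances, then iterate: omnibus F statistics on the
#' observed and Smith-permuted designs, permutation p-values, reference
#' refinement.  Posterior draws and the permutation ensemble are generated
#' once and reused across iterations, so iteration-to-iteration changes
#' reflect only the reference.  The final iteration's statistics feed the
#' permutation FDR estimator.
#'
#' @param cm a \code{\link{CountMatrix}}.
#' @param X covariate(s) of interest (vector or matrix over samples).
#' @param Z optional adjustment covariates; the intercept is implicit.
#' @param alpha target FDR level; default 0.05.
#' @param K posterior draws; default 25.
#' @param rhoGrid power-transform exponents; default 0.5.
#' @param B permutations; default 999.
#' @param refFraction initial reference fraction; default 0.5.
#' @param refExclude fraction of the reference excluded per refinement;
#'   default 0.2.
#' @param iterations refinement iterations; default 6.
#' @param seed integer seed governing draws and permutations.
#' @param filter apply \code{\link{filterTaxa}} defaults first; default
#'   TRUE.
#' @return a \code{\link{ZicoSeqResult}}.
#' @examples
#' ref <- syntheticReference(60, 30, seed = 7)
#' prior <- estimateDirichletPrior(ref)
#' sim <- simulateDataset(ref, prior, simulationConfig(
#'   nPerGroup = 20, signalDensity = 0.1, seed = 11))
#' res <- runZicoSeq(sim@counts, sim@X, B = 99, K = 5, seed = 3)
#' head(as.data.frame(res))
#' @export
runZicoSeq <- function(cm, X, Z = NULL, alpha = 0.05, K = 25L,
                       rhoGrid = 0.5, B = 999L, refFraction = 0.5,
                       refExclude = 0.2, iterations = 6L, seed = 1L,
                       filter = TRUE) {
  stopifnot(is(cm, "CountMatrix"))
  if (filter) cm <- filterTaxa(cm)
  design <- designMatrices(X, Z)
  stopifnot(nrow(design@X) == nSamples(cm))
  set.seed(seed)
  stageSeeds <- sample.int(.Machine$integer.max - 1L, 2L)
  prior <- fitBetaMixture(cm)
  draws <- drawPosteriorProportions(prior, cm, K = K, seed = stageSeeds[1L])
  stat <- pairwiseLogratioVariances(cm, design@Z)
  ref <- selectReference(stat, refFraction)
  ens <- smithPermutations(design, B, seed = stageSeeds[2L])
  itRun <- 0L
  batch <- NULL
  for (it in seq_len(max(iterations, 1L))) {
    batch <- .omnibusBatch(draws@draws, ref@taxonIndices, design, ens, rhoGrid)
    pv <- permutationPvalues(batch$obs, batch$perm)
    itRun <- it
    if (it < iterations) {
      refNew <- refineReference(ref, pv, refExclude)
      if (refNew@exhausted) {
        warning("reference exhausted after ", it, " iteration(s)",
                call. = FALSE)
        ref <- refNew
        break
      }
      ref <- refNew
    }
  }
  fdr <- permutationFdr(batch$obs, batch$perm, alpha)
  methods::new("ZicoSeqResult",
    statistics = unname(batch$obs),
    pvalues = unname(permutationPvalues(batch$obs, batch$perm)),
    qvalues = fdr$qvalues,
    rejected = fdr$rejected,
    reference = ref,
    iterationsRun = itRun,
    taxonNames = taxonNames(cm),
    seed = as.integer(seed),
    config = list(alpha = alpha, K = as.integer(K), rhoGrid = rhoGrid,
                  B = as.integer(B), refFraction = refFraction,
                  refExclude = refExclude, iterations = as.integer(iterations),
                  filter = filter))
}
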