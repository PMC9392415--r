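# Empirical-Bayes inference of the underlying true proportions under a
# per-taxon two-component beta mixture prior.  The marginal distribution of
# a count C given the depth N is a two-component beta-binomial mixture; EM
# on that marginal fits the hyperparameters, and posterior draws / means
# replace observed proportions downstream.

.SHAPE_MIN <- 1e-3
.SHAPE_MAX <- 1e6

# log beta-binomial kernel (choose term excluded): lB(C+a, N-C+b) - lB(a,b)
.lbbKernel <- function(C, N, a, b) {
  lbeta(C + a, N - C + b) - lbeta(a, b)
}

# weighted beta-binomial log-likelihood on log-shape scale
.lbbNeg <- function(u, C, N, w) {
  a <- exp(u[1L]); b <- exp(u[2L])
  -sum(w * .lbbKernel(C, N, a, b))
}

.lbbNegGrad <- function(u, C, N, w) {
  a <- exp(u[1L]); b <- exp(u[2L])
  common <- digamma(a + b) - digamma(N + a + b)
  ga <- sum(w * (digamma(C + a) - digamma(a) + common))
  gb <- sum(w * (digamma(N - C + b) - digamma(b) + common))
  -c(ga * a, gb * b)
}

# Improve the weighted beta-binomial log-likelihood from `start` by a few
# guarded Newton steps on the log-shape scale (gradient and Hessian are
# analytic).  A partial M-step suffices: EM ascent only needs improvement.
.fitWeightedBeta <- function(C, N, w, start, steps = 1L) {
  cur <- log(pmin(pmax(start, .SHAPE_MIN), .SHAPE_MAX))
  fcur <- .lbbNeg(cur, C, N, w)
  lo <- log(.SHAPE_MIN); hi <- log(.SHAPE_MAX)
  for (s in seq_len(steps)) {
    a <- exp(cur[1L]); b <- exp(cur[2L])
    dgab <- digamma(a + b) - digamma(N + a + b)
    tgab <- trigamma(a + b) - trigamma(N + a + b)
    ga <- sum(w * (digamma(C + a) - digamma(a) + dgab))
    gb <- sum(w * (digamma(N - C + b) - digamma(b) + dgab))
    haa <- sum(w * (trigamma(C + a) - trigamma(a) + tgab))
    hbb <- sum(w * (trigamma(N - C + b) - trigamma(b) + tgab))
    hab <- sum(w * tgab)
    # chain rule to u = log(shape)
    gu <- c(ga * a, gb * b)
    H <- matrix(c(haa * a * a + ga * a, hab * a * b,
                  hab * a * b, hbb * b * b + gb * b), 2L, 2L)
    det <- H[1L] * H[4L] - H[2L] * H[3L]
    step <- if (abs(det) > 1e-300)
      c(H[4L] * gu[1L] - H[3L] * gu[2L],
        -H[2L] * gu[1L] + H[1L] * gu[2L]) / det else NULL
    if (!is.null(step) && !all(is.finite(step))) step <- NULL
    # Newton direction for a maximum needs H negative definite; otherwise
    # fall back to a gradient step
    if (is.null(step) || sum(step * gu) >= 0) step <- gu / max(sum(abs(gu)), 1)
    else step <- -step
    improved <- FALSE
    for (half in 0:8) {
      cand <- pmin(pmax(cur + step / 2^half, lo), hi)
      fcand <- .lbbNeg(cand, C, N, w)
      if (is.finite(fcand) && fcand < fcur) {
        cur <- cand; fcur <- fcand; improved <- TRUE
        break
      }
    }
    if (!improved) break
  }
  exp(cur)
}

# method-of-moments beta fit on proportions, heavily clamped
.momBeta <- function(y) {
  mu <- mean(y)
  mu <- min(max(mu, 1e-6), 1 - 1e-6)
  v <- stats::var(y)
  vmax <- mu * (1 - mu)
  if (!is.finite(v) || v <= 0) v <- vmax / 100
  v <- min(v, vmax * 0.99)
  conc <- vmax / v - 1
  conc <- min(max(conc, 1e-2), .SHAPE_MAX / 2)
  c(min(max(mu * conc, .SHAPE_MIN), .SHAPE_MAX),
    min(max((1 - mu) * conc, .SHAPE_MIN), .SHAPE_MAX))
}

# total-variation distance between two beta densities on a grid
.betaTV <- function(a1, b1, a2, b2, grid = 501L) {
  x <- (seq_len(grid) - 0.5) / grid
  sum(abs(dbeta(x, a1, b1) - dbeta(x, a2, b2))) / (2 * grid)
}

# EM fit of the two-component beta-binomial mixture for one taxon.
# Returns parameters, the marginal log-likelihood trace, and flags.
.fitBetaMixtureOne <- function(C, N, maxIter = 200L, tol = 1e-6) {
  lch <- lchoose(N, C)
  marginal <- function(pi, s1, s2) {
    l1 <- log(pi) + .lbbKernel(C, N, s1[1L], s1[2L])
    l2 <- log1p(-pi) + .lbbKernel(C, N, s2[1L], s2[2L])
    hi <- pmax(l1, l2)
    sum(lch + hi + log(exp(l1 - hi) + exp(l2 - hi)))
  }
  # init: split at the median nonzero observed proportion, beta moment fits
  y <- C / N
  mednz <- stats::median(y[C > 0])
  low <- y <= mednz
  s1 <- .momBeta(y[low])
  s2 <- if (any(!low)) .momBeta(y[!low]) else .momBeta(pmin(y + 1e-4, 1))
  pi <- 0.5
  trace <- numeric(0)
  iters <- 0L
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    # component densities at the current parameters serve both the E-step
    # and the marginal log-likelihood for the convergence check
    l1 <- log(pi) + .lbbKernel(C, N, s1[1L], s1[2L])
    l2 <- log1p(-pi) + .lbbKernel(C, N, s2[1L], s2[2L])
    hi <- pmax(l1, l2)
    ll <- sum(lch + hi + log(exp(l1 - hi) + exp(l2 - hi)))
    if (it > 1L && abs(ll - trace[length(trace)]) <
          tol * (abs(trace[length(trace)]) + 1)) {
      trace <- c(trace, ll)
      converged <- TRUE
      break
    }
    trace <- c(trace, ll)
    # E-step
    r <- 1 / (1 + exp(l2 - l1))
    # M-step (generalized: improve, not necessarily maximize)
    pi <- min(max(mean(r), 1e-12), 1 - 1e-12)
    s1 <- .fitWeightedBeta(C, N, r, s1)
    s2 <- .fitWeightedBeta(C, N, 1 - r, s2)
    iters <- it
    # a collapsing mixture converges along a flat ridge; detect it early
    if (it %% 20L == 0L &&
        (pi < 0.01 || pi > 0.99 ||
         .betaTV(s1[1L], s1[2L], s2[1L], s2[2L]) < 0.01))
      break
  }
  if (!converged) trace <- c(trace, marginal(pi, s1, s2))
  collapsed <- pi < 0.01 || pi > 0.99 ||
    .betaTV(s1[1L], s1[2L], s2[1L], s2[2L]) < 0.01
  single <- FALSE
  if (collapsed) {
    # refit a single beta prior on the whole taxon
    s <- .fitWeightedBeta(C, N, rep(1, length(C)), .momBeta(y), steps = 50L)
    s1 <- s2 <- s
    pi <- 1
    single <- TRUE
    trace <- c(trace, marginal(1 - 1e-12, s, s))
    atBound <- any(s <= .SHAPE_MIN * (1 + 1e-8)) ||
      any(s >= .SHAPE_MAX * (1 - 1e-8))
    if (atBound)
      stop("single-beta refit hit the shape bounds", call. = FALSE)
  }
  list(pi = pi, a1 = s1[1L], b1 = s1[2L], a2 = s2[1L], b2 = s2[2L],
       loglik = trace[length(trace)], trace = trace, iterations = iters,
       converged = converged, singleComponent = single)
}

#' Fit the empirical-Bayes beta mixture prior
#'
#' Per taxon, fits by EM the two-component beta-binomial mixture implied
#' by the prior \code{pi * Beta(a1, b1) + (1 - pi) * Beta(a2, b2)} on the
#' true proportion, maximizing the marginal likelihood of the observed
#' (count, depth) pairs.  The E-step computes per-sample responsibilities
#' from the beta-binomial densities; the M-step updates the mixing weight
#' in closed form and the shapes by bounded quasi-Newton steps on the log
#' scale (a generalized EM, so the marginal log-likelihood never
#' decreases).  When the mixture collapses (mixing weight outside
#' [0.01, 0.99] or components within total-variation distance 0.01) a
#' single beta prior is refitted and flagged.
#'
#' @param cm a filtered \code{\link{CountMatrix}}; every taxon must have at
#'   least one nonzero count.
#' @param maxIter maximum EM iterations per taxon; default 200.
#' @param tol relative marginal log-likelihood change declaring
#'   convergence; default 1e-6.
#' @return a \code{\link{BetaMixturePrior}}.
#' @export
fitBetaMixture <- function(cm, maxIter = 200L, tol = 1e-6) {
  stopifnot(is(cm, "CountMatrix"))
  cnt <- counts(cm)
  if (any(colSums(cnt > 0) == 0))
    stop("every taxon must have at least one nonzero count", call. = FALSE)
  N <- cm@depths
  m <- ncol(cnt)
  fits <- lapply(seq_len(m), function(j)
    .fitBetaMixtureOne(cnt[, j], N, maxIter = maxIter, tol = tol))
  pull <- function(f, what) vapply(fits, `[[`, numeric(1L), what)
  methods::new("BetaMixturePrior",
    pi = pull(fits, "pi"), a1 = pull(fits, "a1"), b1 = pull(fits, "b1"),
    a2 = pull(fits, "a2"), b2 = pull(fits, "b2"),
    loglik = pull(fits, "loglik"),
    iterations = vapply(fits, `[[`, integer(1L), "iterations"),
    converged = vapply(fits, `[[`, logical(1L), "converged"),
    singleComponent = vapply(fits, `[[`, logical(1L), "singleComponent"),
    taxonNames = colnames(cnt))
}

#' Posterior mixture weight for one observation
#'
#' The probability that an observation (C, N) belongs to the first prior
#' component, computed through log-beta functions:
#' \code{pi * B(C + a1, N - C + b1) / [pi * B(C + a1, N - C + b1) +
#' (1 - pi) * B(C + a2, N - C + b2)]} after cancelling \code{B(a, b)}
#' normalizers via the prior odds.
#'
#' @param prior a \code{\link{BetaMixturePrior}}.
#' @param C observed count (0 <= C <= N).
#' @param N sample depth.
#' @param taxon taxon index into the prior.
#' @return posterior weight in [0, 1].
#' @export
posteriorMixtureWeights <- function(prior, C, N, taxon) {
  stopifnot(C >= 0, C <= N)
  .postWeights(prior, matrix(C), matrix(N), taxon)[1L]
}

# vectorized posterior weights; C, N matrices/vectors of equal shape.
# Bayes requires the marginal component likelihoods
# B(C + a, N - C + b) / B(a, b); the prior normalizers must be included,
# otherwise a near-point-mass component absorbs every zero count
# regardless of depth and the depth-robustness of the imputation is lost.
.postWeights <- function(prior, C, N, taxon) {
  pi <- prior@pi[taxon]
  if (pi >= 1) return(array(1, dim = dim(as.matrix(C))))
  if (pi <= 0) return(array(0, dim = dim(as.matrix(C))))
  l1 <- log(pi) + lbeta(C + prior@a1[taxon], N - C + prior@b1[taxon]) -
    lbeta(prior@a1[taxon], prior@b1[taxon])
  l2 <- log1p(-pi) + lbeta(C + prior@a2[taxon], N - C + prior@b2[taxon]) -
    lbeta(prior@a2[taxon], prior@b2[taxon])
  1 / (1 + exp(l2 - l1))
}

#' Draw posterior samples of the true proportions
#'
#' For each entry a mixture component is chosen with its posterior weight
#' and a beta variate drawn with the data-updated shapes
#' \code{(C + a, N - C + b)}.  K independent draws are generated from
#' per-draw sub-seeds of one master seed, so increasing K leaves earlier
#' draws unchanged.
#'
#' @param prior a \code{\link{BetaMixturePrior}} fitted on the same taxa.
#' @param cm the \code{\link{CountMatrix}}.
#' @param K number of posterior draws; default 25.
#' @param seed master seed.
#' @return a \code{\link{PosteriorDraws}}.
#' @export
drawPosteriorProportions <- function(prior, cm, K = 25L, seed = 1L) {
  stopifnot(is(prior, "BetaMixturePrior"), is(cm, "CountMatrix"),
            length(prior@pi) == nTaxa(cm), K >= 1)
  cnt <- counts(cm)
  n <- nrow(cnt); m <- ncol(cnt)
  N <- matrix(cm@depths, n, m)
  W <- matrix(0, n, m, dimnames = dimnames(cnt))
  A1 <- matrix(prior@a1, n, m, byrow = TRUE)
  B1 <- matrix(prior@b1, n, m, byrow = TRUE)
  A2 <- matrix(prior@a2, n, m, byrow = TRUE)
  B2 <- matrix(prior@b2, n, m, byrow = TRUE)
  for (j in seq_len(m))
    W[, j] <- .postWeights(prior, cnt[, j], N[, j], j)
  set.seed(seed)
  subSeeds <- sample.int(.Machine$integer.max - 1L, K)
  clamp <- function(x) pmin(pmax(x, 1e-300), 1 - 1e-16)
  draws <- vector("list", K)
  for (k in seq_len(K)) {
    set.seed(subSeeds[k])
    comp1 <- matrix(stats::runif(n * m), n, m) < W
    d <- matrix(0, n, m, dimnames = dimnames(cnt))
    d[comp1] <- stats::rbeta(sum(comp1), (cnt + A1)[comp1], (N - cnt + B1)[comp1])
    d[!comp1] <- stats::rbeta(sum(!comp1), (cnt + A2)[!comp1],
                              (N - cnt + B2)[!comp1])
    draws[[k]] <- clamp(d)
  }
  methods::new("PosteriorDraws", draws = draws, weights = W, K = as.integer(K))
}

#' Closed-form posterior mean proportions
#'
#' The posterior mean of the true proportion under the mixture prior:
#' \code{w * (C + a1)/(N + a1 + b1) + (1 - w) * (C + a2)/(N + a2 + b2)}
#' with \code{w} the posterior mixture weight.  No sampling involved;
#' rows need not sum to one.
#'
#' @param prior a \code{\link{BetaMixturePrior}}.
#' @param cm the \code{\link{CountMatrix}}.
#' @return samples x taxa matrix of posterior means.
#' @export
posteriorMeanProportions <- function(prior, cm) {
  stopifnot(is(prior, "BetaMixturePrior"), is(cm, "CountMatrix"),
            length(prior@pi) == nTaxa(cm))
  cnt <- counts(cm)
  n <- nrow(cnt); m <- ncol(cnt)
  N <- matrix(cm@depths, n, m)
  out <- matrix(0, n, m, dimnames = dimnames(cnt))
  for (j in seq_len(m)) {
    w <- .postWeights(prior, cnt[, j], N[, j], j)
    m1 <- (cnt[, j] + prior@a1[j]) / (N[, j] + prior@a1[j] + prior@b1[j])
    m2 <- (cnt[, j] + prior@a2[j]) / (N[, j] + prior@a2[j] + prior@b2[j])
    out[, j] <- w * m1 + (1 - w) * m2
  }
  out
}
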