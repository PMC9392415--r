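#' Build a simulation configuration
#'
#' Collects all parameters of the semiparametric simulator.  Defaults
#' correspond to the framework's basic two-group comparison: equal group
#' sizes, no confounding, mean sequencing depth 10,000 reads, and two- to
#' four-fold covariate effects on the differential taxa.
#'
#' @param nPerGroup samples per group; default 50.
#' @param covariateType "binary" (two-group) or "continuous"; default binary.
#' @param confounder logical; simulate a confounder acting on the taxa.
#' @param confounderR correlation R between covariate and confounder in
#'   [0, 1); default 0.6 when \code{confounder} is on, else 0.
#' @param signalDensity fraction of differential taxa; default 0.10.
#' @param differentialMode "abundant", "rare" or "any": which abundance
#'   quartile the differential taxa are drawn from.
#' @param direction "balanced" (random effect signs) or "unbalanced"
#'   (all increases, inducing strong compositional effects).
#' @param effectRange range of |a_j| on the log scale; default
#'   \code{c(log(2), log(4))}, i.e. two- to four-fold changes.
#' @param confounderEffectRange range of |b_j|; default
#'   \code{c(log(2), log(3))}.
#' @param confounderDensity fraction of taxa the confounder acts on;
#'   default 0.10.
#' @param noiseSd sd of the taxon-sample noise epsilon; default 0.
#' @param depthMean mean sequencing depth; default 10000.
#' @param depthDispersion negative-binomial size parameter; default 10
#'   (coefficient of variation about 0.33).
#' @param depthFold ratio of group mean depths (1 = no depth confounding).
#' @param seed master seed.
#' @return a \code{\link{SimulationConfig}}.
#' @export
simulationConfig <- function(nPerGroup = 50L,
                             covariateType = c("binary", "continuous"),
                             confounder = FALSE,
                             confounderR = if (confounder) 0.6 else 0,
                             signalDensity = 0.10,
                             differentialMode = c("abundant", "rare", "any"),
                             direction = c("balanced", "unbalanced"),
                             effectRange = c(log(2), log(4)),
                             confounderEffectRange = c(log(2), log(3)),
                             confounderDensity = 0.10,
                             noiseSd = 0,
                             depthMean = 10000,
                             depthDispersion = 10,
                             depthFold = 1,
                             seed = 1L) {
  methods::new("SimulationConfig",
    nPerGroup = as.integer(nPerGroup),
    covariateType = match.arg(covariateType),
    confounder = confounder,
    confounderR = confounderR,
    signalDensity = signalDensity,
    differentialMode = match.arg(differentialMode),
    direction = match.arg(direction),
    effectRange = effectRange,
    confounderEffectRange = confounderEffectRange,
    confounderDensity = confounderDensity,
    noiseSd = noiseSd,
    depthMean = depthMean,
    depthDispersion = depthDispersion,
    depthFold = depthFold,
    seed = as.integer(seed))
}

#' Catalogue of benchmark simulation settings
#'
#' Preset configurations for the benchmark scenarios: global null, balanced
#' and unbalanced differential settings at several sample sizes and taxa
#' numbers, depth confounding, and covariate-confounder correlation.
#'
#' @param id integer 1..10.
#' @param m number of taxa implied by the setting (returned as the
#'   \code{"m"} attribute; the simulator itself takes m from the reference).
#' @param ... overrides passed to \code{\link{simulationConfig}}.
#' @return a \code{\link{SimulationConfig}} with attribute \code{"m"}.
#' @export
settingConfig <- function(id, ...) {
  base <- list(
    `1` = list(nPerGroup = 50L, m = 500L, signalDensity = 0),
    `2` = list(nPerGroup = 50L, m = 500L),
    `3` = list(nPerGroup = 25L, m = 500L),
    `4` = list(nPerGroup = 50L, m = 50L),
    `5` = list(nPerGroup = 50L, m = 500L, depthFold = 4),
    `6` = list(nPerGroup = 50L, m = 500L, direction = "unbalanced",
               differentialMode = "abundant"),
    `7` = list(nPerGroup = 25L, m = 500L, direction = "unbalanced",
               differentialMode = "abundant"),
    `8` = list(nPerGroup = 50L, m = 50L, direction = "unbalanced",
               differentialMode = "abundant"),
    `9` = list(nPerGroup = 50L, m = 500L, confounder = TRUE, confounderR = 0.6),
    `10` = list(nPerGroup = 50L, m = 500L, direction = "unbalanced",
                differentialMode = "abundant", confounder = TRUE,
                confounderR = 0.6)
  )[[as.character(id)]]
  if (is.null(base)) stop("unknown setting id ", id, call. = FALSE)
  m <- base$m
  base$m <- NULL
  args <- utils::modifyList(base, list(...))
  cfg <- do.call(simulationConfig, args)
  attr(cfg, "m") <- m
  cfg
}

#' Generate covariate and confounder
#'
#' Draws a standard-normal confounder Z and a covariate
#' \code{X = sqrt(R^2/(1-R^2)) * Z + N(0,1)}, whose population correlation
#' with Z is exactly R.  A binary covariate is obtained by dichotomizing
#' the continuous X at its sample median (equal group sizes).
#'
#' @param n number of samples.
#' @param R correlation between covariate and confounder, in [0, 1).
#' @param covariateType "binary" or "continuous".
#' @param seed integer seed.
#' @return list with components \code{X} and \code{Z}.
#' @export
generateCovariates <- function(n, R = 0,
                               covariateType = c("binary", "continuous"),
                               seed = 1L) {
  covariateType <- match.arg(covariateType)
  if (R < 0 || R >= 1) stop("R must lie in [0, 1)", call. = FALSE)
  set.seed(seed)
  Z <- rnorm(n)
  X <- sqrt(R^2 / (1 - R^2)) * Z + rnorm(n)
  if (covariateType == "binary") {
    # rank-based split at the median -> exactly equal group sizes for even n
    X <- as.numeric(rank(X, ties.method = "first") > n / 2)
  }
  list(X = X, Z = Z)
}

#' Inject covariate and confounder effects into compositions
#'
#' Multiplies each posterior composition by a log-normal microbial load to
#' form absolute abundances, then applies multiplicative covariate and
#' confounder effects \code{exp(a_j X_i + b_j Z_i + eps_ij)}.
#' Differential taxa are drawn from the upper ("abundant") or lower
#' ("rare") quartile of the mean-abundance distribution, or from all taxa
#' ("any"); non-differential taxa have a_j = 0.
#'
#' @param P a \code{\link{ProportionMatrix}} (or matrix) of compositions.
#' @param X covariate vector.
#' @param Z confounder vector (ignored unless the config has a confounder).
#' @param config a \code{\link{SimulationConfig}}.
#' @param seed integer seed.
#' @return list with the effect-modified absolute abundances \code{C2}
#'   (strictly positive matrix), the logical \code{truth} vector and the
#'   coefficient vectors \code{a} and \code{b}.
#' @export
injectEffects <- function(P, X, Z, config, seed = 1L) {
  if (is(P, "ProportionMatrix")) P <- proportions(P)
  n <- nrow(P); m <- ncol(P)
  stopifnot(length(X) == n, length(Z) == n)
  set.seed(seed)
  S <- exp(rnorm(n))                       # microbial load, log(S) ~ N(0,1)
  C1 <- P * S
  nDiff <- round(config@signalDensity * m)
  meanAb <- colMeans(P)
  candidates <- switch(config@differentialMode,
    abundant = which(meanAb >= stats::quantile(meanAb, 0.75, type = 1)),
    rare = which(meanAb <= stats::quantile(meanAb, 0.25, type = 1)),
    any = seq_len(m))
  if (length(candidates) < nDiff)
    stop("the ", config@differentialMode, " quartile holds only ",
         length(candidates), " taxa; cannot place ", nDiff,
         " differential taxa", call. = FALSE)
  diffIdx <- if (nDiff > 0) sort(sample(candidates, nDiff)) else integer(0)
  truth <- seq_len(m) %in% diffIdx
  a <- numeric(m)
  if (nDiff > 0) {
    mag <- stats::runif(nDiff, config@effectRange[1L], config@effectRange[2L])
    sgn <- if (config@direction == "balanced")
      sample(c(-1, 1), nDiff, replace = TRUE) else rep(1, nDiff)
    a[diffIdx] <- mag * sgn
  }
  b <- numeric(m)
  if (config@confounder) {
    nConf <- round(config@confounderDensity * m)
    if (nConf > 0) {
      confIdx <- sample.int(m, nConf)
      bmag <- stats::runif(nConf, config@confounderEffectRange[1L],
                           config@confounderEffectRange[2L])
      b[confIdx] <- bmag * sample(c(-1, 1), nConf, replace = TRUE)
    }
  }
  eta <- outer(X, a) + outer(Z, b)
  if (config@noiseSd > 0)
    eta <- eta + matrix(rnorm(n * m, sd = config@noiseSd), n, m)
  C2 <- C1 * exp(eta)
  dimnames(C2) <- dimnames(P)
  list(C2 = C2, truth = truth, a = a, b = b, S = S)
}

#' Internal: negative-binomial depth draws with zero-redraw
#' @keywords internal
.drawDepths <- function(mu, size) {
  D <- rnbinom(length(mu), mu = mu, size = size)
  for (attempt in seq_len(100L)) {
    z <- D == 0
    if (!any(z)) return(D)
    D[z] <- rnbinom(sum(z), mu = mu[z], size = size)
  }
  stop("failed to draw positive sequencing depths in 100 attempts",
       call. = FALSE)
}

#' Generate sequencing counts from absolute abundances
#'
#' Renormalizes the effect-modified abundances to compositions, draws
#' per-sample sequencing depths from a negative binomial (with a group
#' depth-fold multiplier for depth-confounded settings; depths of zero are
#' redrawn) and generates reads from a multinomial.
#'
#' @param C2 strictly positive samples x taxa abundance matrix.
#' @param config a \code{\link{SimulationConfig}}.
#' @param group binary 0/1 group label per sample (group 1 receives the
#'   \code{depthFold} multiplier).
#' @param seed integer seed.
#' @return list with the \code{\link{CountMatrix}} \code{counts}, the
#'   drawn depths \code{D} and the compositions \code{P2}.
#' @export
generateCounts <- function(C2, config, group = NULL, seed = 1L) {
  stopifnot(all(C2 > 0))
  n <- nrow(C2); m <- ncol(C2)
  if (is.null(group)) group <- rep(0L, n)
  stopifnot(length(group) == n)
  P2 <- C2 / rowSums(C2)
  set.seed(seed)
  mu <- config@depthMean * ifelse(group == 1, config@depthFold, 1)
  D <- .drawDepths(mu, config@depthDispersion)
  cnt <- matrix(0, n, m, dimnames = dimnames(C2))
  for (i in seq_len(n))
    cnt[i, ] <- stats::rmultinom(1L, D[i], P2[i, ])[, 1L]
  if (is.null(rownames(cnt))) rownames(cnt) <- paste0("sim", seq_len(n))
  if (is.null(colnames(cnt))) colnames(cnt) <- paste0("taxon", seq_len(m))
  list(counts = countMatrix(cnt), D = D, P2 = P2)
}

#' Simulate a dataset from the semiparametric framework
#'
#' Chains the framework's stages: draw template samples from the reference
#' (with replacement), sample posterior compositions under the Dirichlet
#' prior, generate covariate and confounder, inject effects, and generate
#' sequencing counts.  Fully reproducible from \code{config@seed}.
#'
#' @param reference a filtered \code{\link{CountMatrix}} of reference
#'   samples.
#' @param prior a \code{\link{DirichletPrior}} fitted on \code{reference}.
#' @param config a \code{\link{SimulationConfig}}.
#' @return a \code{\link{SimulatedDataset}}.
#' @export
simulateDataset <- function(reference, prior, config) {
  stopifnot(is(reference, "CountMatrix"), is(prior, "DirichletPrior"),
            is(config, "SimulationConfig"))
  n <- 2L * config@nPerGroup
  set.seed(config@seed)
  stageSeeds <- sample.int(.Machine$integer.max - 1L, 5L)
  set.seed(stageSeeds[1L])
  templates <- sample.int(nSamples(reference), n, replace = TRUE)
  P <- samplePosteriorComposition(reference, prior, templates,
                                  seed = stageSeeds[2L])
  cov <- generateCovariates(n, R = config@confounderR,
                            covariateType = config@covariateType,
                            seed = stageSeeds[3L])
  eff <- injectEffects(P, cov$X, cov$Z, config, seed = stageSeeds[4L])
  group <- if (config@covariateType == "binary") cov$X else
    as.numeric(rank(cov$X, ties.method = "first") > n / 2)
  gen <- generateCounts(eff$C2, config, group = group, seed = stageSeeds[5L])
  methods::new("SimulatedDataset",
    counts = gen$counts,
    X = cov$X,
    Z = if (config@confounder) cov$Z else numeric(0),
    truth = eff$truth,
    trueCompositions = methods::new("ProportionMatrix", proportions = gen$P2),
    templateIndices = as.integer(templates),
    config = config,
    intermediates = list(S = eff$S, a = eff$a, b = eff$b, D = gen$D,
                         Zfull = cov$Z))
}

#' Generate a synthetic pseudo-reference count table
#'
#' Stands in for a large real reference dataset (synthetic): per-taxon
#' Dirichlet hyperparameters are drawn from a long-tailed log-normal so
#' mean relative abundances span several orders of magnitude, compositions
#' from the resulting Dirichlet, depths from a negative binomial with mean
#' 10,000 reads, and counts from a multinomial.  Taxa failing the default
#' prevalence/abundance filter are dropped, so the output is ready to use
#' as a simulation reference.
#'
#' @param nSamples number of reference samples (>= 10); default 200.
#' @param nTaxa number of taxa requested (>= 10).  Hyperparameters are
#'   calibrated on an oversampled pilot table (candidates failing the
#'   filter are resampled), the \code{nTaxa} most abundant passing
#'   candidates are retained, and the final table is generated from the
#'   retained hyperparameters alone, so compositions are complete and
#'   depths match the negative-binomial draw exactly.
#' @param seed integer seed.
#' @param concentration total Dirichlet concentration controlling
#'   between-sample variability; default 100 (strong overdispersion,
#'   realistic sparsity).
#' @return a \code{\link{CountMatrix}}.
#' @export
syntheticReference <- function(nSamples = 200L, nTaxa = 100L, seed = 1L,
                               concentration = 100) {
  stopifnot(nSamples >= 10, nTaxa >= 10)
  set.seed(seed)
  simulate <- function(gamma) {
    m <- length(gamma)
    P <- matrix(rgamma(nSamples * m, shape = rep(gamma, each = nSamples)),
                nSamples, m)
    P <- pmax(P, 1e-300)
    P <- P / rowSums(P)
    D <- .drawDepths(rep(10000, nSamples), size = 10)
    cnt <- matrix(0, nSamples, m)
    for (i in seq_len(nSamples))
      cnt[i, ] <- stats::rmultinom(1L, D[i], P[i, ])[, 1L]
    cnt
  }
  passes <- function(cnt) {
    colMeans(cnt > 0) >= 0.10 &
      apply(cnt / rowSums(cnt), 2L, max) >= 0.002
  }
  # pilot: oversample candidate taxa, resample the hyperparameters of
  # candidates failing the filter until enough pass
  mCand <- 3L * nTaxa
  rawGamma <- stats::rlnorm(mCand, meanlog = 0, sdlog = 3)
  cnt <- simulate(rawGamma / sum(rawGamma) * concentration)
  ok <- passes(cnt)
  for (round in seq_len(20L)) {
    if (sum(ok) >= nTaxa) break
    rawGamma[!ok] <- stats::rlnorm(sum(!ok), meanlog = 0, sdlog = 3)
    cnt <- simulate(rawGamma / sum(rawGamma) * concentration)
    ok <- passes(cnt)
  }
  passIdx <- which(ok)
  meanAb <- colMeans(cnt / rowSums(cnt))[passIdx]
  keep <- sort(passIdx[order(-meanAb)][seq_len(min(nTaxa, length(passIdx)))])
  # final table from the retained hyperparameters only
  gamma <- rawGamma[keep] / sum(rawGamma[keep]) * concentration
  cnt <- simulate(gamma)
  ok <- passes(cnt)          # renormalization only raises abundances;
  cnt <- cnt[, ok, drop = FALSE]  # residual failures are rare borderline taxa
  cnt <- cnt[rowSums(cnt) > 0, , drop = FALSE]
  dimnames(cnt) <- list(paste0("ref", seq_len(nrow(cnt))),
                        paste0("taxon", seq_len(ncol(cnt))))
  countMatrix(cnt)
}
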