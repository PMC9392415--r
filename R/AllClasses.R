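#' @import methods
NULL

#' CountMatrix: taxa counts per sample
#'
#' The universal input object: a samples x taxa matrix of non-negative
#' integer read counts together with per-sample library sizes (sequencing
#' depths).  Depths are stored separately from the counts because taxa
#' filtering keeps the original library size: the total number of reads
#' sequenced for a sample does not change when rare taxa are dropped from
#' testing, and downstream beta-binomial models condition on that total.
#'
#' @slot counts numeric matrix, samples in rows, taxa in columns, with
#'   unique row and column names.
#' @slot depths integer-valued numeric vector of per-sample totals; equals
#'   the row sums at construction and stays fixed under taxa filtering
#'   (hence \code{depths >= rowSums(counts)} is the class invariant).
#'
#' @aliases CountMatrix
#' @exportClass CountMatrix
setClass("CountMatrix",
  slots = c(counts = "matrix", depths = "numeric"))

setValidity("CountMatrix", function(object) {
  cnt <- object@counts
  msg <- character()
  if (!is.numeric(cnt)) msg <- c(msg, "counts must be numeric")
  if (any(cnt < 0)) msg <- c(msg, "counts must be non-negative")
  if (any(abs(cnt - round(cnt)) > 1e-8)) msg <- c(msg, "counts must be integers")
  if (is.null(rownames(cnt)) || is.null(colnames(cnt)))
    msg <- c(msg, "counts must carry sample (row) and taxon (column) names")
  else {
    if (anyDuplicated(rownames(cnt))) msg <- c(msg, "duplicate sample ids")
    if (anyDuplicated(colnames(cnt))) msg <- c(msg, "duplicate taxon ids")
  }
  if (length(object@depths) != nrow(cnt))
    msg <- c(msg, "depths length must match the number of samples")
  else if (any(object@depths + 1e-8 < rowSums(cnt)))
    msg <- c(msg, "depths must be at least the per-sample count totals")
  if (length(msg)) msg else TRUE
})

#' ProportionMatrix: relative abundances per sample
#'
#' Samples x taxa matrix of relative abundances in [0, 1].  For a complete
#' table each row sums to one; for a sub-composition (a filtered table
#' normalized by the full library size) row sums may fall below one, which
#' the validity method permits.  Row sums above one are never allowed.
#'
#' @slot proportions numeric matrix in [0, 1] with sample/taxon dimnames.
#'
#' @exportClass ProportionMatrix
setClass("ProportionMatrix", slots = c(proportions = "matrix"))

setValidity("ProportionMatrix", function(object) {
  p <- object@proportions
  msg <- character()
  if (any(p < 0) || any(p > 1 + 1e-12)) msg <- c(msg, "proportions must lie in [0, 1]")
  rs <- rowSums(p)
  if (any(rs <= 0)) msg <- c(msg, "rows with zero total are disallowed")
  if (any(rs > 1 + 1e-12)) msg <- c(msg, "row sums must not exceed 1")
  if (length(msg)) msg else TRUE
})

#' DirichletPrior: fitted Dirichlet hyperparameters
#'
#' @slot gamma positive hyperparameter vector, one entry per taxon.
#' @slot loglik maximized Dirichlet-multinomial marginal log-likelihood.
#' @slot converged logical convergence flag of the optimizer.
#' @slot iterations function evaluations used.
#'
#' @exportClass DirichletPrior
setClass("DirichletPrior",
  slots = c(gamma = "numeric", loglik = "numeric",
            converged = "logical", iterations = "integer"))

setValidity("DirichletPrior", function(object) {
  if (any(object@gamma <= 0)) "all gamma must be positive" else TRUE
})

#' SimulationConfig: parameters of the semiparametric simulator
#'
#' Holds every knob of the simulation framework; see
#' \code{\link{simulationConfig}} for defaults and units.
#'
#' @slot nPerGroup samples per group (binary design) or half the total n.
#' @slot covariateType "binary" or "continuous".
#' @slot confounder logical; whether a confounder acts on the taxa.
#' @slot confounderR correlation R between covariate and confounder.
#' @slot signalDensity fraction of taxa that are truly differential.
#' @slot differentialMode "abundant", "rare" or "any".
#' @slot direction "balanced" or "unbalanced" signs of the effects.
#' @slot effectRange range for the covariate effect magnitude |a_j| (log scale).
#' @slot confounderEffectRange range for |b_j| (log scale).
#' @slot confounderDensity fraction of taxa the confounder acts on.
#' @slot noiseSd standard deviation of the taxon-sample level noise.
#' @slot depthMean mean sequencing depth (reads).
#' @slot depthDispersion negative-binomial size parameter of the depths.
#' @slot depthFold ratio of group mean depths (depth confounding).
#' @slot seed integer master seed.
#'
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  slots = c(nPerGroup = "integer", covariateType = "character",
            confounder = "logical", confounderR = "numeric",
            signalDensity = "numeric", differentialMode = "character",
            direction = "character", effectRange = "numeric",
            confounderEffectRange = "numeric", confounderDensity = "numeric",
            noiseSd = "numeric", depthMean = "numeric",
            depthDispersion = "numeric", depthFold = "numeric",
            seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nPerGroup < 1) msg <- c(msg, "nPerGroup must be >= 1")
  if (!object@covariateType %in% c("binary", "continuous"))
    msg <- c(msg, "covariateType must be 'binary' or 'continuous'")
  if (object@confounderR < 0 || object@confounderR >= 1)
    msg <- c(msg, "confounderR must lie in [0, 1)")
  if (object@signalDensity < 0 || object@signalDensity >= 1)
    msg <- c(msg, "signalDensity must lie in [0, 1)")
  if (!object@differentialMode %in% c("abundant", "rare", "any"))
    msg <- c(msg, "differentialMode must be 'abundant', 'rare' or 'any'")
  if (!object@direction %in% c("balanced", "unbalanced"))
    msg <- c(msg, "direction must be 'balanced' or 'unbalanced'")
  if (length(object@effectRange) != 2 || any(object@effectRange < 0))
    msg <- c(msg, "effectRange must be two non-negative numbers")
  if (length(object@confounderEffectRange) != 2 ||
      any(object@confounderEffectRange < 0))
    msg <- c(msg, "confounderEffectRange must be two non-negative numbers")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@depthMean <= 0) msg <- c(msg, "depthMean must be positive")
  if (object@depthDispersion <= 0) msg <- c(msg, "depthDispersion must be positive")
  if (object@depthFold < 1) msg <- c(msg, "depthFold must be >= 1")
  if (length(msg)) msg else TRUE
})

#' SimulatedDataset: output of the semiparametric simulator
#'
#' @slot counts \code{CountMatrix} of simulated reads.
#' @slot X covariate of interest (vector over samples).
#' @slot Z confounder vector (length zero when no confounder is simulated).
#' @slot truth logical vector marking the truly differential taxa.
#' @slot trueCompositions \code{ProportionMatrix} of post-effect compositions.
#' @slot templateIndices reference samples used as templates.
#' @slot config the resolved \code{SimulationConfig}.
#' @slot intermediates list of intermediate quantities (microbial loads,
#'   effect coefficients, drawn depths) for diagnostics.
#'
#' @exportClass SimulatedDataset
setClass("SimulatedDataset",
  slots = c(counts = "CountMatrix", X = "numeric", Z = "numeric",
            truth = "logical", trueCompositions = "ProportionMatrix",
            templateIndices = "integer", config = "SimulationConfig",
            intermediates = "list"))

#' BetaMixturePrior: empirical-Bayes two-component beta prior
#'
#' Per-taxon hyperparameters of the mixture prior
#' pi * Beta(a1, b1) + (1 - pi) * Beta(a2, b2) on the true proportion,
#' fitted by EM on the marginal beta-binomial likelihood.
#'
#' @slot pi mixing weights in [0, 1].
#' @slot a1,b1,a2,b2 positive beta shape parameters (vectors over taxa).
#' @slot loglik per-taxon maximized marginal log-likelihood.
#' @slot iterations EM iterations used per taxon.
#' @slot converged per-taxon convergence flags.
#' @slot singleComponent TRUE where the mixture collapsed and a single
#'   beta prior was refitted.
#' @slot taxonNames taxon identifiers the prior was fitted on.
#'
#' @exportClass BetaMixturePrior
setClass("BetaMixturePrior",
  slots = c(pi = "numeric", a1 = "numeric", b1 = "numeric",
            a2 = "numeric", b2 = "numeric", loglik = "numeric",
            iterations = "integer", converged = "logical",
            singleComponent = "logical", taxonNames = "character"))

setValidity("BetaMixturePrior", function(object) {
  msg <- character()
  if (any(object@pi < 0 | object@pi > 1)) msg <- c(msg, "pi must lie in [0, 1]")
  if (any(c(object@a1, object@b1, object@a2, object@b2) <= 0))
    msg <- c(msg, "beta shapes must be positive")
  m <- length(object@pi)
  if (any(lengths(list(object@a1, object@b1, object@a2, object@b2,
                       object@taxonNames)) != m))
    msg <- c(msg, "per-taxon slots must have equal length")
  if (length(msg)) msg else TRUE
})

#' PosteriorDraws: posterior samples of the true proportions
#'
#' @slot draws list of K samples x taxa matrices of posterior proportions,
#'   all entries strictly inside (0, 1).
#' @slot weights samples x taxa matrix of posterior mixture weights.
#' @slot K number of draws.
#'
#' @exportClass PosteriorDraws
setClass("PosteriorDraws",
  slots = c(draws = "list", weights = "matrix", K = "integer"))

setValidity("PosteriorDraws", function(object) {
  msg <- character()
  if (length(object@draws) != object@K) msg <- c(msg, "draws must have length K")
  if (any(object@weights < 0 | object@weights > 1))
    msg <- c(msg, "weights must lie in [0, 1]")
  for (d in object@draws)
    if (any(d <= 0) || any(d >= 1)) {
      msg <- c(msg, "draws must lie strictly in (0, 1)")
      break
    }
  if (length(msg)) msg else TRUE
})

#' ReferenceSet: taxa presumed non-differential
#'
#' The reference taxa whose cumulative proportion serves as the
#' normalization denominator of the ratio responses.
#'
#' @slot taxonIndices indices (into the tested taxa) of the reference set.
#' @slot stat per-taxon median log-ratio residual variance used for ranking.
#' @slot iteration refinement iteration this set belongs to (0 = initial).
#' @slot exhausted TRUE when a refinement step was refused because it would
#'   have emptied the set.
#'
#' @exportClass ReferenceSet
setClass("ReferenceSet",
  slots = c(taxonIndices = "integer", stat = "numeric",
            iteration = "integer", exhausted = "logical"))

setValidity("ReferenceSet", function(object) {
  if (length(object@taxonIndices) == 0) "reference set must be non-empty"
  else if (anyDuplicated(object@taxonIndices)) "duplicate reference indices"
  else TRUE
})

#' DesignMatrices: covariate-of-interest and adjustment designs
#'
#' @slot X n x p design of the covariate(s) of interest.
#' @slot Z n x q design of adjustment covariates; always contains the
#'   intercept column.
#'
#' @exportClass DesignMatrices
setClass("DesignMatrices", slots = c(X = "matrix", Z = "matrix"))

setValidity("DesignMatrices", function(object) {
  n <- nrow(object@X)
  p <- ncol(object@X)
  q <- ncol(object@Z)
  msg <- character()
  if (nrow(object@Z) != n) msg <- c(msg, "X and Z must have equal row counts")
  if (n <= p + q) msg <- c(msg, "need n > p + q")
  if (qr(cbind(object@Z, object@X))$rank < p + q)
    msg <- c(msg, "(X, Z) must be jointly of full column rank")
  if (length(msg)) msg else TRUE
})

#' FStatistics: per-taxon omnibus F statistics
#'
#' @slot perRho length(rhoGrid) x taxa matrix of K-draw-averaged F values.
#' @slot omnibus per-taxon maximum over the rho grid.
#' @slot rhoGrid the power-transform exponents examined.
#'
#' @exportClass FStatistics
setClass("FStatistics",
  slots = c(perRho = "matrix", omnibus = "numeric", rhoGrid = "numeric"))

#' PermutationEnsemble: Smith-permuted designs
#'
#' @slot B number of permutations.
#' @slot perms n x B matrix of row permutations applied to the residuals.
#' @slot Xperm list of B permuted designs X^b = Xhat + E^b.
#'
#' @exportClass PermutationEnsemble
setClass("PermutationEnsemble",
  slots = c(B = "integer", perms = "matrix", Xperm = "list"))

#' ZicoSeqResult: differential abundance test results
#'
#' @slot statistics per-taxon omnibus F statistics (observed design).
#' @slot pvalues per-taxon permutation p-values.
#' @slot qvalues per-taxon permutation-FDR estimates, mapped back from the
#'   sorted order.
#' @slot rejected logical rejection indicator at level alpha.
#' @slot reference the final \code{ReferenceSet}.
#' @slot iterationsRun reference-refinement iterations actually executed.
#' @slot taxonNames taxon identifiers (after filtering).
#' @slot seed the seed the run is reproducible from.
#' @slot config list of the resolved tuning parameters.
#'
#' @exportClass ZicoSeqResult
setClass("ZicoSeqResult",
  slots = c(statistics = "numeric", pvalues = "numeric", qvalues = "numeric",
            rejected = "logical", reference = "ReferenceSet",
            iterationsRun = "integer", taxonNames = "character",
            seed = "integer", config = "list"))

#' EvaluationSummary: benchmark results over simulation runs
#'
#' @slot summary per-method data.frame with observed FDR (mean FDP, or the
#'   any-discovery fraction under the global null), mean TPR and run counts.
#' @slot perRun per-run, per-method FDP/TPR records.
#' @slot settingId identifier of the simulation setting.
#' @slot config the \code{SimulationConfig} the runs used.
#'
#' @exportClass EvaluationSummary
setClass("EvaluationSummary",
  slots = c(summary = "data.frame", perRun = "data.frame",
            settingId = "character", config = "SimulationConfig"))
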