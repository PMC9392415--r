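# Evaluation harness: Wilcoxon baselines under different normalizations,
# BH adjustment, FDP/TPR metrics, the star/rank scoring system, a p-value
# stability metric, and a settings runner.

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up BH adjustment (monotone, capped at one); a thin named
#' wrapper over \code{stats::p.adjust}.
#'
#' @param p vector of p-values in [0, 1].
#' @return adjusted p-values.
#' @export
bhAdjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Wilcoxon rank-sum differential abundance baseline
#'
#' Normalizes the counts by the chosen strategy and runs a two-sided
#' Wilcoxon rank-sum test per taxon between the two groups.  Taxa constant
#' after normalization receive p = 1.
#'
#' @param cm a \code{\link{CountMatrix}}.
#' @param group binary group labels (two levels).
#' @param normalization "tss" (proportions), "rarefy" (subsample to the
#'   minimum depth, then proportions), "gmpr" (counts divided by the GMPR
#'   size factor) or "posterior_mean" (empirical-Bayes posterior mean
#'   proportions).
#' @param seed seed for the rarefaction draw.
#' @return named per-taxon p-value vector.
#' @export
wilcoxonDaa <- function(cm, group,
                        normalization = c("tss", "rarefy", "gmpr",
                                          "posterior_mean"),
                        seed = 1L) {
  normalization <- match.arg(normalization)
  group <- as.factor(group)
  stopifnot(nlevels(group) == 2L, length(group) == nSamples(cm))
  if (any(table(group) == 0)) stop("both groups must be non-empty", call. = FALSE)
  mat <- switch(normalization,
    tss = counts(cm) / cm@depths,
    rarefy = {
      rc <- rarefyCounts(cm, min(rowSums(counts(cm))), seed = seed)
      counts(rc) / rc@depths
    },
    gmpr = counts(cm) / gmprSizeFactors(cm),
    posterior_mean = posteriorMeanProportions(fitBetaMixture(cm), cm))
  g1 <- group == levels(group)[1L]
  p <- apply(mat, 2L, function(v) {
    if (max(v) == min(v)) return(1)
    suppressWarnings(stats::wilcox.test(v[g1], v[!g1])$p.value)
  })
  p[is.na(p)] <- 1
  p
}

#' False discovery proportion and true positive rate
#'
#' \code{FDP = FP / (TP + FP)} (zero when nothing is rejected) and
#' \code{TPR = TP / (TP + FN)} (\code{NA} under the global null, where no
#' positives exist).
#'
#' @param rejected logical rejection vector.
#' @param truth logical ground-truth vector of the same length.
#' @return named numeric vector \code{c(FDP =, TPR =)}.
#' @export
evaluateFdpTpr <- function(rejected, truth) {
  stopifnot(length(rejected) == length(truth))
  TP <- sum(rejected & truth)
  FP <- sum(rejected & !truth)
  FN <- sum(!rejected & truth)
  fdp <- if (TP + FP == 0) 0 else FP / (TP + FP)
  tpr <- if (TP + FN == 0) NA_real_ else TP / (TP + FN)
  c(FDP = fdp, TPR = tpr)
}

#' Star/rank scoring of benchmarked methods
#'
#' Per setting, observed FDR in (0, 0.05], (0.05, 0.1], (0.1, 0.2] and
#' above 0.2 scores 3, 2, 1 and 0 stars (boundary values fall in the
#' better bin), and methods are ranked by mean TPR (higher TPR, higher
#' rank; ties averaged).  Total star and rank scores are themselves
#' converted to ranks and summed into an overall score, weighting
#' false-positive control and power equally.
#'
#' @param summaries data.frame with columns \code{method}, \code{setting},
#'   \code{observed_fdr}, \code{mean_tpr}.
#' @return data.frame with per-method total \code{fdr_score},
#'   \code{tpr_score} and \code{overall_score}, plus the per-setting stars
#'   in the attribute \code{"stars"}.
#' @export
scoreMethods <- function(summaries) {
  stopifnot(all(c("method", "setting", "observed_fdr", "mean_tpr") %in%
                  names(summaries)),
            length(unique(summaries$method)) >= 2)
  starsOf <- function(fdr) {
    ifelse(fdr <= 0.05, 3L, ifelse(fdr <= 0.1, 2L, ifelse(fdr <= 0.2, 1L, 0L)))
  }
  summaries$stars <- starsOf(summaries$observed_fdr)
  tprRank <- stats::ave(summaries$mean_tpr, summaries$setting,
                        FUN = function(x) rank(x, ties.method = "average",
                                               na.last = "keep"))
  summaries$tpr_rank <- tprRank
  agg <- do.call(rbind, lapply(split(summaries, summaries$method), function(d) {
    data.frame(method = d$method[1L],
               fdr_score = sum(d$stars),
               tpr_score = sum(d$tpr_rank, na.rm = TRUE))
  }))
  agg$fdr_rank <- rank(agg$fdr_score, ties.method = "average")
  agg$tpr_rank <- rank(agg$tpr_score, ties.method = "average")
  agg$overall_score <- agg$fdr_rank + agg$tpr_rank
  agg <- agg[order(-agg$overall_score), ]
  rownames(agg) <- NULL
  attr(agg, "stars") <- summaries[, c("method", "setting", "observed_fdr",
                                      "stars", "mean_tpr", "tpr_rank")]
  agg
}

#' Stability of p-values under filtering
#'
#' Spearman rank correlation of the p-values a method assigns to the taxa
#' shared between an unfiltered and a strictly filtered analysis.
#'
#' @param pUnfiltered,pFiltered named or positional p-value vectors.
#' @param sharedTaxa indices (into each vector) of the common taxa;
#'   at least 3.
#' @return Spearman rho, or NA when a vector is constant.
#' @export
stabilityCorrelation <- function(pUnfiltered, pFiltered, sharedTaxa) {
  stopifnot(length(sharedTaxa) >= 3)
  x <- pUnfiltered[sharedTaxa]
  y <- pFiltered[sharedTaxa]
  if (max(x) == min(x) || max(y) == min(y)) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

#' Built-in DAA method callables for benchmarking
#'
#' Returns a named list of functions \code{f(cm, group, seed)} that each
#' yield a logical rejection vector at the 5% FDR level: the package's
#' permutation test (its internal permutation FDR) and Wilcoxon baselines
#' (BH-adjusted at 0.05).
#'
#' @param alpha target FDR level; default 0.05.
#' @param B,K,iterations tuning of the permutation test (kept small for
#'   benchmarking throughput).
#' @return named list of callables.
#' @export
benchmarkMethods <- function(alpha = 0.05, B = 99L, K = 10L,
                             iterations = 6L) {
  wilcox <- function(norm) {
    force(norm)
    function(cm, group, seed) {
      p <- wilcoxonDaa(cm, group, normalization = norm, seed = seed)
      bhAdjust(p) <= alpha
    }
  }
  list(
    zicoseq = function(cm, group, seed) {
      res <- runZicoSeq(cm, group, alpha = alpha, B = B, K = K,
                        iterations = iterations, seed = seed, filter = FALSE)
      res@rejected
    },
    tss_wilcox = wilcox("tss"),
    rarefy_wilcox = wilcox("rarefy"),
    gmpr_wilcox = wilcox("gmpr"))
}

#' Run a benchmark setting
#'
#' Simulates \code{nRuns} datasets under a settings-catalogue entry (or a
#' custom \code{\link{SimulationConfig}}), applies each method, and
#' aggregates FDP/TPR.  Under the global null the observed FDR column
#' reports the fraction of runs making any discovery.  Failing runs are
#' logged and skipped.
#'
#' @param setting integer 1..10 (see \code{\link{settingConfig}}) or a
#'   \code{\link{SimulationConfig}}.
#' @param methods named list of callables \code{f(cm, group, seed)}
#'   returning logical rejections; default \code{\link{benchmarkMethods}}.
#' @param nRuns simulation runs; default 50.
#' @param seed master seed.
#' @param reference optional \code{\link{CountMatrix}} reference; defaults
#'   to a \code{\link{syntheticReference}} with the setting's taxa number.
#' @param m taxa number used when generating the default reference
#'   (overrides the setting's own m; useful for scaled-down runs).
#' @return an \code{\link{EvaluationSummary}}.
#' @export
runSetting <- function(setting, methods = benchmarkMethods(), nRuns = 50L,
                       seed = 1L, reference = NULL, m = NULL) {
  cfg <- if (is(setting, "SimulationConfig")) setting
         else settingConfig(setting)
  settingId <- if (is(setting, "SimulationConfig")) "custom"
               else as.character(setting)
  if (is.null(m)) m <- attr(cfg, "m")
  if (is.null(m)) m <- 100L
  if (is.null(reference))
    reference <- syntheticReference(200L, m, seed = seed)
  prior <- estimateDirichletPrior(reference)
  set.seed(seed)
  runSeeds <- sample.int(.Machine$integer.max - 1L, nRuns)
  rows <- list()
  for (run in seq_len(nRuns)) {
    cfgRun <- cfg
    cfgRun@seed <- runSeeds[run]
    sim <- simulateDataset(reference, prior, cfgRun)
    cmF <- try(filterTaxa(sim@counts), silent = TRUE)
    if (inherits(cmF, "try-error")) {
      message("run ", run, " skipped: ", attr(cmF, "condition")$message)
      next
    }
    keptTruth <- sim@truth[match(taxonNames(cmF), taxonNames(sim@counts))]
    for (meth in names(methods)) {
      rej <- try(methods[[meth]](cmF, sim@X, runSeeds[run]), silent = TRUE)
      if (inherits(rej, "try-error")) {
        message("run ", run, " method ", meth, " failed: ",
                attr(rej, "condition")$message)
        next
      }
      met <- evaluateFdpTpr(rej, keptTruth)
      rows[[length(rows) + 1L]] <- data.frame(
        run = run, method = meth, FDP = met[["FDP"]], TPR = met[["TPR"]],
        anyDiscovery = any(rej))
    }
  }
  perRun <- do.call(rbind, rows)
  globalNull <- cfg@signalDensity == 0
  summary <- do.call(rbind, lapply(split(perRun, perRun$method), function(d) {
    data.frame(
      method = d$method[1L],
      observed_fdr = if (globalNull) mean(d$anyDiscovery) else mean(d$FDP),
      mean_tpr = if (globalNull) NA_real_ else mean(d$TPR, na.rm = TRUE),
      runs = nrow(d))
  }))
  rownames(summary) <- NULL
  methods::new("EvaluationSummary", summary = summary, perRun = perRun,
               settingId = settingId, config = cfg)
}
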