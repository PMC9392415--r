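#' Accessor generics
#'
#' Small accessor generics for the package's S4 containers.  Slot access
#' from user code should always go through these.
#'
#' @param object an object of one of the package's S4 classes.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("counts", function(object) standardGeneric("counts"))

#' @rdname accessors
#' @export
setGeneric("sampleDepths", function(object) standardGeneric("sampleDepths"))

#' @rdname accessors
#' @export
setGeneric("sampleNames", function(object) standardGeneric("sampleNames"))

#' @rdname accessors
#' @export
setGeneric("taxonNames", function(object) standardGeneric("taxonNames"))

#' @rdname accessors
#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))

#' @rdname accessors
#' @export
setGeneric("nTaxa", function(object) standardGeneric("nTaxa"))

#' @rdname accessors
#' @export
setGeneric("proportions", function(object) standardGeneric("proportions"))

#' @rdname accessors
#' @export
setGeneric("referenceTaxa", function(object) standardGeneric("referenceTaxa"))

#' @rdname accessors
#' @export
setGeneric("statistics", function(object) standardGeneric("statistics"))

#' @rdname accessors
#' @export
setGeneric("pvalues", function(object) standardGeneric("pvalues"))

#' @rdname accessors
#' @export
setGeneric("qvalues", function(object) standardGeneric("qvalues"))

#' @rdname accessors
#' @export
setGeneric("rejectedTaxa", function(object) standardGeneric("rejectedTaxa"))

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))

# -- CountMatrix -------------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("counts", "CountMatrix", function(object) object@counts)

#' @rdname accessors
#' @export
setMethod("sampleDepths", "CountMatrix", function(object) {
  stats::setNames(object@depths, rownames(object@counts))
})

#' @rdname accessors
#' @export
setMethod("sampleNames", "CountMatrix", function(object) rownames(object@counts))

#' @rdname accessors
#' @export
setMethod("taxonNames", "CountMatrix", function(object) colnames(object@counts))

#' @rdname accessors
#' @export
setMethod("nSamples", "CountMatrix", function(object) nrow(object@counts))

#' @rdname accessors
#' @export
setMethod("nTaxa", "CountMatrix", function(object) ncol(object@counts))

setMethod("show", "CountMatrix", function(object) {
  cat("CountMatrix:", nSamples(object), "samples x", nTaxa(object), "taxa\n")
  d <- object@depths
  cat("  depths: min", min(d), "| median", stats::median(d), "| max", max(d), "\n")
  cat("  sparsity:", sprintf("%.1f%%", 100 * mean(object@counts == 0)), "zeros\n")
})

# -- ProportionMatrix --------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("proportions", "ProportionMatrix", function(object) object@proportions)

#' @rdname accessors
#' @export
setMethod("sampleNames", "ProportionMatrix",
          function(object) rownames(object@proportions))

#' @rdname accessors
#' @export
setMethod("taxonNames", "ProportionMatrix",
          function(object) colnames(object@proportions))

setMethod("show", "ProportionMatrix", function(object) {
  cat("ProportionMatrix:", nrow(object@proportions), "samples x",
      ncol(object@proportions), "taxa\n")
})

# -- SimulatedDataset --------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("counts", "SimulatedDataset", function(object) object@counts@counts)

#' @rdname accessors
#' @export
setMethod("groundTruth", "SimulatedDataset", function(object) object@truth)

setMethod("show", "SimulatedDataset", function(object) {
  cat("SimulatedDataset:", nSamples(object@counts), "samples x",
      nTaxa(object@counts), "taxa,",
      sum(object@truth), "differential taxa\n")
  cat("  covariate:", object@config@covariateType,
      if (object@config@confounder)
        sprintf("(confounder, R = %.2f)", object@config@confounderR)
      else "(no confounder)", "\n")
})

# -- ReferenceSet ------------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("referenceTaxa", "ReferenceSet", function(object) object@taxonIndices)

setMethod("show", "ReferenceSet", function(object) {
  cat("ReferenceSet:", length(object@taxonIndices), "taxa (iteration",
      object@iteration, ")\n")
})

# -- ZicoSeqResult -----------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("statistics", "ZicoSeqResult", function(object) {
  stats::setNames(object@statistics, object@taxonNames)
})

#' @rdname accessors
#' @export
setMethod("pvalues", "ZicoSeqResult", function(object) {
  stats::setNames(object@pvalues, object@taxonNames)
})

#' @rdname accessors
#' @export
setMethod("qvalues", "ZicoSeqResult", function(object) {
  stats::setNames(object@qvalues, object@taxonNames)
})

#' @rdname accessors
#' @export
setMethod("rejectedTaxa", "ZicoSeqResult", function(object) {
  stats::setNames(object@rejected, object@taxonNames)
})

#' @rdname accessors
#' @export
setMethod("referenceTaxa", "ZicoSeqResult",
          function(object) object@reference@taxonIndices)

setMethod("show", "ZicoSeqResult", function(object) {
  cat("ZicoSeqResult:", length(object@statistics), "taxa tested,",
      sum(object@rejected), "rejected at alpha =",
      object@config$alpha, "\n")
  cat("  reference:", length(object@reference@taxonIndices), "taxa after",
      object@iterationsRun, "iteration(s);",
      object@config$B, "permutations, K =", object@config$K, "draws\n")
})

# -- BetaMixturePrior --------------------------------------------------------

setMethod("show", "BetaMixturePrior", function(object) {
  cat("BetaMixturePrior:", length(object@pi), "taxa;",
      sum(object@singleComponent), "single-component fallback(s)\n")
})

setMethod("show", "EvaluationSummary", function(object) {
  cat("EvaluationSummary (setting ", object@settingId, "):\n", sep = "")
  print(object@summary, row.names = FALSE)
})

#' Coerce a ZicoSeqResult to a data.frame
#'
#' @param x a \code{ZicoSeqResult}.
#' @param ... ignored.
#' @return data.frame with columns taxon, F_omnibus, p_perm, q_perm,
#'   rejected and in_reference.
#' @export
as.data.frame.ZicoSeqResult <- function(x, ...) {
  data.frame(
    taxon = x@taxonNames,
    F_omnibus = x@statistics,
    p_perm = x@pvalues,
    q_perm = x@qvalues,
    rejected = x@rejected,
    in_reference = seq_along(x@statistics) %in% x@reference@taxonIndices,
    row.names = NULL)
}
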