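# Reference taxa selection.  Taxa whose pairwise log ratios show small
# residual variance after adjusting for Z are unlikely to be differential;
# their cumulative proportion serves as the normalization denominator.

#' Median pairwise log-ratio residual variances
#'
#' For every ordered taxon pair (j, k) the log ratio
#' \code{log(C_j + 1) - log(C_k + 1)} is regressed on the adjustment design
#' Z (intercept included) and the residual variance \code{RSS / (n - q)}
#' recorded; the per-taxon statistic is the median over partners k.  Log
#' ratios involving differential taxa inherit the covariate effect into
#' their error term, inflating the statistic.
#'
#' @param cm a \code{\link{CountMatrix}}.
#' @param Z adjustment design matrix with intercept, or NULL for
#'   intercept-only.
#' @return named per-taxon numeric vector of median residual variances.
#' @export
pairwiseLogratioVariances <- function(cm, Z = NULL) {
  stopifnot(is(cm, "CountMatrix"), nTaxa(cm) >= 2)
  cnt <- counts(cm)
  n <- nrow(cnt)
  if (is.null(Z)) Z <- matrix(1, n, 1L)
  Z <- as.matrix(Z)
  q <- qr(Z)$rank
  if (n <= q) stop("need more samples than adjustment covariates", call. = FALSE)
  L <- log(cnt + 1)
  QZ <- qr.Q(qr(Z))
  R <- L - QZ %*% crossprod(QZ, L)        # residuals of each log column
  G <- crossprod(R)                        # m x m residual cross-products
  rss <- diag(G)
  # residual sum of squares of the pair (j, k): rss_j + rss_k - 2 G_jk
  m <- ncol(cnt)
  pairVar <- (outer(rss, rss, "+") - 2 * G) / (n - q)
  diag(pairVar) <- NA_real_
  stats::setNames(apply(pairVar, 1L, stats::median, na.rm = TRUE),
                  colnames(cnt))
}

#' Select the initial reference set
#'
#' Keeps the \code{floor(fraction * m)} taxa with the smallest ranking
#' statistic; ties are broken by taxon index (stable).
#'
#' @param stat per-taxon ranking statistic (smaller = more reference-like).
#' @param fraction fraction of taxa to select, in (0, 1]; default 0.5.
#' @return a \code{\link{ReferenceSet}}.
#' @export
selectReference <- function(stat, fraction = 0.5) {
  stopifnot(fraction > 0, fraction <= 1)
  m <- length(stat)
  k <- floor(fraction * m)
  if (k < 1) stop("selection fraction yields an empty reference", call. = FALSE)
  ord <- order(stat, seq_len(m))
  methods::new("ReferenceSet",
    taxonIndices = sort(ord[seq_len(k)]),
    stat = unname(stat), iteration = 0L, exhausted = FALSE)
}

#' Refine the reference set by excluding significant members
#'
#' Removes the \code{ceiling(excludeFraction * |ref|)} current reference
#' members with the smallest p-values (ties by taxon index).  Removed taxa
#' never re-enter.  If removal would empty the set the input is returned
#' with the \code{exhausted} flag raised.
#'
#' @param ref a \code{\link{ReferenceSet}}.
#' @param pvalues per-taxon p-value vector (full taxa length).
#' @param excludeFraction fraction of the current reference to drop;
#'   default 0.2.
#' @return a \code{\link{ReferenceSet}}.
#' @export
refineReference <- function(ref, pvalues, excludeFraction = 0.2) {
  stopifnot(is(ref, "ReferenceSet"),
            excludeFraction >= 0, excludeFraction < 1)
  idx <- ref@taxonIndices
  if (any(is.na(pvalues[idx])))
    stop("p-values must be defined for all reference members", call. = FALSE)
  nDrop <- ceiling(excludeFraction * length(idx))
  if (nDrop >= length(idx)) {
    warning("refinement would empty the reference set; keeping current set",
            call. = FALSE)
    return(methods::new("ReferenceSet", taxonIndices = idx, stat = ref@stat,
                        iteration = ref@iteration + 1L, exhausted = TRUE))
  }
  if (nDrop > 0) {
    ord <- order(pvalues[idx], idx)
    idx <- sort(idx[-ord[seq_len(nDrop)]])
  }
  methods::new("ReferenceSet", taxonIndices = idx, stat = ref@stat,
               iteration = ref@iteration + 1L, exhausted = FALSE)
}
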