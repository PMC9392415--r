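#' Construct a CountMatrix
#'
#' @param counts numeric matrix of non-negative integer counts.  By default
#'   samples are rows and taxa columns; set \code{orientation} to
#'   \code{"taxa-in-rows"} for the transposed layout common in OTU tables.
#' @param orientation \code{"samples-in-rows"} (default) or
#'   \code{"taxa-in-rows"}.
#' @param depths optional per-sample totals; defaults to the row sums.  Only
#'   the package's own filtering should ever supply depths larger than the
#'   row sums.
#' @return a validated \code{\link{CountMatrix}}.
#' @examples
#' cm <- countMatrix(matrix(1:6, 2, 3,
#'   dimnames = list(c("s1", "s2"), c("t1", "t2", "t3"))))
#' sampleDepths(cm)
#' @export
countMatrix <- function(counts, orientation = c("samples-in-rows", "taxa-in-rows"),
                        depths = NULL) {
  orientation <- match.arg(orientation)
  counts <- as.matrix(counts)
  if (orientation == "taxa-in-rows") counts <- t(counts)
  if (!is.numeric(counts))
    stop("count table must be numeric", call. = FALSE)
  if (any(counts < 0))
    stop("count table contains negative entries", call. = FALSE)
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("count table contains non-integer entries", call. = FALSE)
  counts <- round(counts)
  storage.mode(counts) <- "double"
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("sample", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("taxon", seq_len(ncol(counts)))
  if (is.null(depths)) depths <- rowSums(counts)
  methods::new("CountMatrix", counts = counts, depths = unname(depths))
}

#' Read a count table from disk
#'
#' Reads a tab- or comma-delimited count table (one id header row, one id
#' column; the delimiter is sniffed from the header line) or a BIOM file
#' (via the \pkg{biomformat} package) into a \code{\link{CountMatrix}}.
#'
#' @param path file path to a .tsv/.csv/.txt table or a .biom file.
#' @param orientation whether samples or taxa are in rows of the file.
#'   BIOM files are taxa-by-sample by convention and ignore this argument.
#' @return a \code{\link{CountMatrix}} normalized to samples x taxa.
#' @export
loadCountTable <- function(path,
                           orientation = c("samples-in-rows", "taxa-in-rows")) {
  orientation <- match.arg(orientation)
  if (grepl("\\.biom$", path, ignore.case = TRUE)) {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("reading BIOM files requires the 'biomformat' package", call. = FALSE)
    b <- biomformat::read_biom(path)
    mat <- as(biomformat::biom_data(b), "matrix")
    return(countMatrix(mat, orientation = "taxa-in-rows"))
  }
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                          check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate ids in the first column of ", path, call. = FALSE)
  mat <- as.matrix(df[, -1L, drop = FALSE])
  if (anyDuplicated(colnames(mat)))
    stop("duplicate ids in the header of ", path, call. = FALSE)
  if (!is.numeric(mat))
    stop("non-numeric entries in ", path, call. = FALSE)
  rownames(mat) <- ids
  countMatrix(mat, orientation = orientation)
}

#' Write a CountMatrix to a delimited file
#'
#' @param cm a \code{\link{CountMatrix}}.
#' @param path output file path; tab-delimited, samples in rows.
#' @export
writeCountTable <- function(cm, path) {
  df <- data.frame(sample = sampleNames(cm), counts(cm), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter rare taxa from a count table
#'
#' Removes taxa with prevalence (fraction of samples with a nonzero count)
#' below \code{minPrevalence} or a maximum per-sample proportion below
#' \code{minMaxProp}.  Both comparisons are strict: a taxon sitting exactly
#' on a threshold is retained.  Per-sample depths are left untouched so the
#' beta-binomial totals downstream still reflect the full library size.
#'
#' @param cm a \code{\link{CountMatrix}}.
#' @param minPrevalence prevalence threshold in [0, 1]; default 0.10.
#' @param minMaxProp maximum-proportion threshold in [0, 1]; default 0.002.
#' @return the filtered \code{\link{CountMatrix}} (taxon order preserved).
#' @export
filterTaxa <- function(cm, minPrevalence = 0.10, minMaxProp = 0.002) {
  stopifnot(is(cm, "CountMatrix"),
            minPrevalence >= 0, minPrevalence <= 1,
            minMaxProp >= 0, minMaxProp <= 1)
  cnt <- counts(cm)
  prev <- colMeans(cnt > 0)
  maxprop <- apply(cnt / cm@depths, 2L, max)
  keep <- prev >= minPrevalence & maxprop >= minMaxProp
  if (!any(keep))
    stop("all taxa removed by filtering", call. = FALSE)
  methods::new("CountMatrix", counts = cnt[, keep, drop = FALSE],
               depths = cm@depths)
}

#' Total-sum-scaling proportions
#'
#' Divides each sample's counts by its library size (the stored depth).
#' For an unfiltered table rows sum to one; for a filtered table they sum
#' to the retained fraction of reads.
#'
#' @param cm a \code{\link{CountMatrix}} with strictly positive depths.
#' @return a \code{\link{ProportionMatrix}}.
#' @export
tssProportions <- function(cm) {
  stopifnot(is(cm, "CountMatrix"))
  zero <- cm@depths <= 0
  if (any(zero))
    stop("zero-depth sample(s): ",
         paste(sampleNames(cm)[zero], collapse = ", "), call. = FALSE)
  methods::new("ProportionMatrix", proportions = counts(cm) / cm@depths)
}

#' Rarefy a count table to a common depth
#'
#' Subsamples each sample's reads without replacement (multivariate
#' hypergeometric) to exactly \code{targetDepth}.  Samples with fewer reads
#' than the target are dropped with a warning.
#'
#' @param cm a \code{\link{CountMatrix}}.
#' @param targetDepth integer target depth (>= 1).
#' @param seed integer seed; the subsampling is reproducible.
#' @return a \code{\link{CountMatrix}} whose rows all sum to
#'   \code{targetDepth}.
#' @export
rarefyCounts <- function(cm, targetDepth, seed = 1L) {
  stopifnot(is(cm, "CountMatrix"), targetDepth >= 1)
  cnt <- counts(cm)
  tot <- rowSums(cnt)
  keep <- tot >= targetDepth
  if (!any(keep))
    stop("no sample reaches the target depth ", targetDepth, call. = FALSE)
  if (!all(keep))
    warning(sum(!keep), " sample(s) below depth ", targetDepth, " dropped",
            call. = FALSE)
  cnt <- cnt[keep, , drop = FALSE]
  m <- ncol(cnt)
  set.seed(seed)
  out <- t(apply(cnt, 1L, function(row) {
    if (sum(row) == targetDepth) return(row)
    reads <- rep.int(seq_len(m), row)
    tabulate(reads[sample.int(length(reads), targetDepth)], nbins = m)
  }))
  dimnames(out) <- dimnames(cnt)
  methods::new("CountMatrix", counts = out, depths = rowSums(out))
}

#' GMPR size factors
#'
#' Geometric mean of pairwise ratios: for each sample the geometric mean,
#' over all other samples, of the median count ratio across taxa observed
#' in both samples.  Robust to zero inflation because only shared nonzero
#' taxa enter each pairwise median.  Factors are rescaled to have geometric
#' mean one so that normalized counts stay on the original scale.
#'
#' @param cm a \code{\link{CountMatrix}} with at least two samples.
#' @return named positive numeric vector of per-sample size factors.
#' @export
gmprSizeFactors <- function(cm) {
  stopifnot(is(cm, "CountMatrix"), nSamples(cm) >= 2)
  cnt <- counts(cm)
  n <- nrow(cnt)
  logmed <- matrix(NA_real_, n, n)
  for (i in seq_len(n - 1L)) {
    for (k in seq.int(i + 1L, n)) {
      shared <- cnt[i, ] > 0 & cnt[k, ] > 0
      if (!any(shared))
        stop("samples ", rownames(cnt)[i], " and ", rownames(cnt)[k],
             " share no nonzero taxon", call. = FALSE)
      # medians of the count ratios themselves; with an even number of
      # shared taxa the two directions are not reciprocal, so compute both
      logmed[i, k] <- log(stats::median(cnt[i, shared] / cnt[k, shared]))
      logmed[k, i] <- log(stats::median(cnt[k, shared] / cnt[i, shared]))
    }
  }
  logf <- rowMeans(logmed, na.rm = TRUE)
  f <- exp(logf - mean(logf))
  stats::setNames(f, rownames(cnt))
}

#' Harmonize sequencing depth between two groups
#'
#' Drops samples with fewer than 100 reads, then tests for a depth
#' difference between the two groups with a two-sided Wilcoxon rank-sum
#' test.  If the difference is significant the table is rarefied: to the
#' minimum depth when that minimum exceeds 30,000 reads, otherwise to
#' 30,000 (samples below the target are dropped).  Otherwise the input is
#' returned unchanged.
#'
#' @param cm a \code{\link{CountMatrix}}.
#' @param group binary group label per sample (two levels).
#' @param alpha significance level of the depth test; default 0.05.
#' @param seed seed for the rarefaction.
#' @return a \code{\link{CountMatrix}}.
#' @export
harmonizeDepthConfounding <- function(cm, group, alpha = 0.05, seed = 1L) {
  stopifnot(is(cm, "CountMatrix"), length(group) == nSamples(cm))
  group <- as.factor(group)
  if (nlevels(group) != 2L) stop("exactly two groups required", call. = FALSE)
  keep <- cm@depths >= 100
  if (!all(keep)) {
    cm <- methods::new("CountMatrix",
                       counts = counts(cm)[keep, , drop = FALSE],
                       depths = cm@depths[keep])
    group <- droplevels(group[keep])
    if (nlevels(group) != 2L)
      stop("a group was emptied by the 100-read filter", call. = FALSE)
  }
  d <- cm@depths
  p <- suppressWarnings(
    stats::wilcox.test(d[group == levels(group)[1L]],
                       d[group == levels(group)[2L]])$p.value)
  if (is.na(p) || p >= alpha) return(cm)
  target <- if (min(d) > 30000) min(d) else 30000
  rarefyCounts(cm, target, seed = seed)
}
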