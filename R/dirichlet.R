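#' Dirichlet-multinomial marginal log-likelihood
#'
#' @param gamma positive hyperparameter vector (length = taxa).
#' @param cnt samples x taxa count matrix.
#' @return the marginal log-likelihood (multinomial coefficient omitted;
#'   it does not depend on gamma).
#' @keywords internal
.dmLoglik <- function(gamma, cnt) {
  theta <- sum(gamma)
  N <- rowSums(cnt)
  sum(lgamma(theta) - lgamma(N + theta)) +
    sum(lgamma(sweep(cnt, 2L, gamma, "+")) ) -
    nrow(cnt) * sum(lgamma(gamma))
}

.dmGradient <- function(gamma, cnt) {
  theta <- sum(gamma)
  N <- rowSums(cnt)
  common <- sum(digamma(theta) - digamma(N + theta))
  common + colSums(digamma(sweep(cnt, 2L, gamma, "+"))) -
    nrow(cnt) * digamma(gamma)
}

#' Method-of-moments initializer for the Dirichlet hyperparameters
#'
#' Matches the per-taxon mean proportions and uses the median implied
#' concentration from the proportion variances.
#' @keywords internal
.dmMomInit <- function(cnt) {
  Y <- cnt / rowSums(cnt)
  pbar <- colMeans(Y)
  v <- apply(Y, 2L, stats::var)
  ok <- v > 0 & pbar > 0 & pbar < 1
  theta <- if (any(ok))
    stats::median(pmax(pbar[ok] * (1 - pbar[ok]) / v[ok] - 1, 1e-2))
  else 1
  pmax(pbar, 1e-8) * theta
}

#' Fit a Dirichlet prior to a reference count table
#'
#' Maximum-likelihood estimation of the Dirichlet hyperparameters under
#' the Dirichlet-multinomial marginal model for the observed counts,
#' by quasi-Newton (L-BFGS-B) ascent on the log hyperparameters with an
#' analytic gradient and a method-of-moments start.
#'
#' @param reference a \code{\link{CountMatrix}} of reference samples
#'   (ideally pre-filtered with \code{\link{filterTaxa}}).
#' @param maxIter maximum optimizer iterations; default 500.
#' @param tol gradient-norm tolerance declaring convergence; default 1e-3
#'   on the log scale (per-coordinate gradients scale with n).
#' @return a \code{\link{DirichletPrior}}.
#' @export
estimateDirichletPrior <- function(reference, maxIter = 500L, tol = 1e-3) {
  stopifnot(is(reference, "CountMatrix"), nSamples(reference) >= 2)
  cnt <- counts(reference)
  g0 <- .dmMomInit(cnt)
  negll <- function(u) -.dmLoglik(exp(u), cnt)
  neggr <- function(u) -.dmGradient(exp(u), cnt) * exp(u)
  fit <- stats::optim(log(g0), negll, neggr, method = "L-BFGS-B",
                      lower = log(1e-8), upper = log(1e8),
                      control = list(maxit = maxIter, factr = 1e4))
  gamma <- exp(fit$par)
  grad <- .dmGradient(gamma, cnt) * gamma
  # relative gradient criterion: scale by n so tol is size-free
  converged <- fit$convergence == 0L ||
    sqrt(mean(grad^2)) / nrow(cnt) < tol
  if (!converged)
    stop("Dirichlet-multinomial MLE did not converge (last log-likelihood ",
         format(-fit$value), "; gamma range ",
         paste(format(range(gamma)), collapse = " .. "), ")", call. = FALSE)
  ll <- .dmLoglik(gamma, cnt)
  if (ll + 1e-8 < .dmLoglik(g0, cnt))
    stop("optimizer failed to improve on the moment initializer", call. = FALSE)
  methods::new("DirichletPrior",
               gamma = stats::setNames(gamma, taxonNames(reference)),
               loglik = ll, converged = TRUE,
               iterations = as.integer(fit$counts[["function"]]))
}

#' Sample posterior compositions for template samples
#'
#' The posterior of the underlying composition of a reference sample under
#' the Dirichlet prior is Dirichlet with parameter \code{counts + gamma};
#' this draws one composition per requested template.
#'
#' @param reference the \code{\link{CountMatrix}} the prior was fitted on.
#' @param prior a \code{\link{DirichletPrior}}.
#' @param templateIndices integer vector of reference rows to use as
#'   templates (repeats allowed).
#' @param seed integer seed.
#' @return a \code{\link{ProportionMatrix}} with one strictly positive
#'   composition per template.
#' @export
samplePosteriorComposition <- function(reference, prior, templateIndices,
                                       seed = 1L) {
  stopifnot(is(reference, "CountMatrix"), is(prior, "DirichletPrior"),
            all(templateIndices >= 1),
            all(templateIndices <= nSamples(reference)),
            length(prior@gamma) == nTaxa(reference))
  cnt <- counts(reference)
  m <- ncol(cnt)
  set.seed(seed)
  P <- matrix(0, length(templateIndices), m)
  for (i in seq_along(templateIndices)) {
    shape <- cnt[templateIndices[i], ] + prior@gamma
    g <- rgamma(m, shape = shape)
    g <- pmax(g, 1e-300)  # guard against underflow for tiny shapes
    P[i, ] <- g / sum(g)
  }
  dimnames(P) <- list(paste0("sim", seq_along(templateIndices)),
                      colnames(cnt))
  methods::new("ProportionMatrix", proportions = P)
}
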