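# ZicoSeq

Differential abundance analysis (DAA) for microbiome sequencing data asks
which taxa's abundances covary with a phenotype or exposure. Two features
of 16S/metagenomic count tables defeat naive testing: the data are
**compositional** (sequencing yields relative, not absolute, abundances, so
a genuine change in a few taxa induces apparent changes everywhere else)
and **zero-inflated** (most entries are zeros, a mix of true absences and
shallow sequencing). This package implements a permutation-based DAA
procedure built for exactly these data, together with a semiparametric
simulation framework and a benchmarking harness to measure false discovery
rate (FDR) control and power.

## The method

For counts `C_ij` with library sizes `N_i`, let `mu_ij` be the latent true
proportion of taxon `j` in sample `i`. The procedure combines four pieces:

1. **Empirical-Bayes imputation of the true proportions.** Each taxon gets
   a two-component beta mixture prior
   `mu_ij ~ pi_j Beta(a_j1, b_j1) + (1 - pi_j) Beta(a_j2, b_j2)`,
   fitted by EM on the marginal beta-binomial likelihood of
   `(C_ij, N_i)`. Posterior samples `mu*_ij` replace the observed
   proportions, which stabilizes zeros and removes sequencing-depth
   artifacts.
2. **Reference-taxa normalization.** A data-driven reference set of
   presumed non-differential taxa is selected by regressing every pairwise
   log ratio `log(C_j + 1) - log(C_k + 1)` on the adjustment covariates and
   ranking taxa by the median residual variance; the ratio
   `mu*_ij / mu_i^C`, with `mu_i^C` the cumulative reference proportion,
   absorbs compositional effects.
3. **Omnibus power-transformed F statistic.** For design matrices `X`
   (covariates of interest) and `Z` (adjustment, intercept included), with
   responses `y = (mu*_j / mu^C)^rho`,

   `F_rho,j = [y'(H_XZ - H_Z)y / p] / [y'(I - H_XZ)y / (n - p - q)]`,

   averaged over `K` posterior draws and maximized over a grid of
   exponents `rho` (default `{0.5}`).
4. **Permutation FDR control.** Covariate-respecting null designs are
   built by the Smith procedure (permute the residuals of `X` on `Z`, add
   back the fitted values). With observed statistics sorted descending,
   the estimator `q_(j) = [#{(k,b): F^b_k >= F_(j)} / B] / j` yields a
   step-up rejection rule at the target FDR; the reference set is refined
   over several iterations by excluding its most significant members.

The simulator draws template samples from a reference dataset, infers
their compositions under a Dirichlet posterior, injects covariate,
confounder and library-size effects parametrically, and regenerates reads
— so simulated data keep the sparsity, overdispersion and correlation
structure of real microbiome data while the ground truth is known.

## Worked example

```r
library(ZicoSeq)

ref   <- syntheticReference(nSamples = 200, nTaxa = 100, seed = 42)
prior <- estimateDirichletPrior(ref)
cfg   <- simulationConfig(nPerGroup = 50, signalDensity = 0.2, seed = 11)
sim   <- simulateDataset(ref, prior, cfg)

cm  <- filterTaxa(sim@counts)
res <- runZicoSeq(cm, sim@X, B = 199, K = 10, seed = 1)
res
```

```
CountMatrix: 100 samples x 96 taxa
  depths: min 4724 | median 9671 | max 23263
  sparsity: 44.6% zeros
ZicoSeqResult: 96 taxa tested, 12 rejected at alpha = 0.05
  reference: 15 taxa after 6 iteration(s); 199 permutations, K = 10 draws
```

```r
df <- as.data.frame(res)
head(df[order(df$q_perm), ], 8)
```

```
     taxon F_omnibus p_perm   q_perm rejected in_reference
3   taxon4      25.5  0.005 0.000000     TRUE        FALSE
4   taxon5      48.1  0.005 0.000000     TRUE        FALSE
19 taxon20      40.0  0.005 0.000000     TRUE        FALSE
68 taxon69      24.3  0.005 0.000000     TRUE        FALSE
69 taxon70      19.2  0.005 0.000000     TRUE        FALSE
6   taxon7      14.5  0.005 0.000718     TRUE        FALSE
94 taxon96      15.3  0.005 0.000838     TRUE        FALSE
36 taxon37      13.1  0.010 0.004397     TRUE        FALSE
```

Twenty taxa were truly differential (signal density 0.2); comparing the
rejection set to the ground truth:

```r
truth <- groundTruth(sim)[match(taxonNames(cm), taxonNames(sim@counts))]
evaluateFdpTpr(rejectedTaxa(res), truth)
#> FDP TPR
#> 0.0 0.6
```

All 12 discoveries are true positives (false discovery proportion 0) and
12 of the 20 planted signals are recovered (true positive rate 0.6) at the
5% FDR target.

A command-line front end over the same functions ships in
`inst/scripts/zicoseq-cli.R` with subcommands `filter`, `simulate`,
`impute`, `test` and `bench`.

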