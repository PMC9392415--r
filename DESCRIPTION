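Package: ZicoSeq
Title: Permutation-Based Differential Abundance Analysis for Zero-Inflated
    Compositional Microbiome Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Differential abundance analysis for taxa-by-sample microbiome
    count tables. Observed proportions are replaced by posterior draws from a
    per-taxon empirical-Bayes two-component beta mixture, compositional
    effects are addressed by normalizing to the cumulative proportion of a
    data-driven reference taxa set selected from pairwise log-ratio residual
    variances, association is assessed by an omnibus power-transformed
    F statistic averaged over posterior draws, and false discovery rate
    control uses a covariate-respecting (Smith) permutation scheme. The
    package also ships a semiparametric simulation framework (empirical-Bayes
    Dirichlet posterior resampling of reference templates with parametric
    covariate, confounder and sequencing-depth effects) and a benchmarking
    harness with Wilcoxon baselines under TSS, rarefaction and GMPR
    normalization.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils
Suggests:
    biomformat,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
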