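Package: twinlong
Title: Simulation and Analysis of Genetic Effects on Longitudinal Twin
    Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study statistical methods for detecting genetic main
    and gene-by-age interaction effects on a longitudinal phenotype measured
    in twin pairs. Provides a generative simulator for twin growth
    trajectories (segmented linear growth with twin-structured random
    intercepts and slopes, Mendelian single-SNP genotypes), four summary
    phenotypes (mean, slope, intercept, trapezoidal area under the curve),
    a classical twin ACE variance-components model with heritability
    estimation, family and three-level hierarchical linear mixed models,
    marginal models fit by generalized estimating equations with
    exchangeable, autoregressive and unstructured working correlations and
    robust sandwich variances, a Bayesian longitudinal twin
    variance-components model fit by MCMC, and a replicate harness
    estimating power, type I error, bias and heritability recovery.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    lme4,
    pracma,
    rjags,
    coda,
    MASS,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
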