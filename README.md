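# twinlong

Statistical methods for detecting genetic effects on a longitudinal
phenotype measured in twin pairs — and a simulation laboratory for
comparing them.

Longitudinal twin cohorts carry two correlation structures at once:
repeated measurements within a child over time, and the familial
correlation between co-twins (stronger for monozygotic than dizygotic
pairs). Standard software models one of them and simplifies the other.
This package implements the main analysis strategies side by side, plus a
generative simulator with known genetic effects, so that power, type I
error, bias and heritability recovery of each simplification can be
measured. It is aimed at statistical geneticists and epidemiologists
planning or interpreting longitudinal family analyses.

## The model

Phenotypes (BMI, kg/m²) for twin *j* of pair *i* at visit *k* follow a
segmented linear growth model:

    Y_ijk = (β0 + β0_ij) + βS·S_ij + βG·G_ij + (βT + βT_ij)·T_ijk
            + βT′·T′_ijk + βGT·G_ij·T_ijk + ε_ijk,   ε_ijk ~ N(0, σE²)

with age `T` in months, segmented age `T′ = max(T − 6, 0)` after the
first two visits (a 6-month knot), sex `S ∈ {0,1}`, and an additive SNP
genotype `G ∈ {0,1,2}` transmitted Mendelianly from Hardy–Weinberg
parents (MAF 0.3). Random intercepts `β0_ij` and age slopes `βT_ij` have
the classical twin covariance structure: variance `σA² + σC²`, within-pair
covariance `σA² + σC²` (MZ) or `σA²/2 + σC²` (DZ), and the `τA², τC²`
analogues for slopes. Heritability is `h² = σA²/(σA² + σC² + σE²)`.

Analyses implemented:

| family | functions | simplification |
|---|---|---|
| summary statistic + twin model | `summarize_trajectories()`, `fit_ace()` | collapses time |
| summary statistic + family LMM | `fit_family_lmm()` | collapses time, pools zygosity |
| marginal GEE (exch/AR-1/unstructured, sandwich) | `fit_gee()` | ignores the twin correlation |
| three-level hierarchical LMM | `fit_three_level()` | pools zygosity |
| Bayesian twin variance components (MCMC) | `run_mcmc()` | constant correlation over time |

`run_replicates()` / `power_curve()` / `estimate_table()` orchestrate
replicate studies over the nine built-in generating models
(`sim_model("1")` … `sim_model("4b")`).

## Worked example

Simulate the default cohort (226 DZ + 168 MZ pairs, six visits at 1, 6,
18, 30, 48, 60 months) under a genotype effect of 0.3 on the average
phenotype, and fit the classical twin model to the per-child mean:

```r
library(twinlong)
dat <- simulate_twin_data(sim_model("2d"), seed = 2024)
fit <- fit_ace(summarize_trajectories(dat, "mean"), response = "mean")
fit
#> Twin ACE model fit (ML), response: mean | pairs: 394
#>         term estimate     se      z         p
#>  (Intercept)  12.2208 0.1838 66.506 0.0000000
#>          sex   0.3337 0.1872  1.782 0.0746740
#>     genotype   0.5324 0.1610  3.306 0.0009455
#> variance components: sigmaA2 = 4.876 , sigmaC2 = 2.3543 , sigmaE2 = 0.3608
#> heritability h2 = 0.6423 | logLik = -1659.64 | converged: TRUE
```

On this dataset the genotype effect (true value 0.3 per minor allele) is
estimated at 0.53 ± 0.16 and clearly detected (p < 0.001). Note the small
residual component: the mean over six visits averages the occasion-level
noise down to σE²/6 ≈ 0.375, so the heritability *of the mean phenotype*
concentrates near 4.5/7.125 ≈ 0.63, above the single-occasion value of
0.5 — see the vignette for why this matters when interpreting summary
phenotypes.

A small replicate study comparing methods on the same simulated datasets:

```r
rep <- run_replicates(sim_model("2d"), c("ace_mean", "gee_unstructured"),
                      n_reps = 25, seed = 2024)
rep
#> Replicate evaluation: 25 replicates, 226 DZ + 168 MZ pairs
#> Rejection proportions (test term per method):
#>            method test_term rejection  mc_se n_used n_requested n_failed
#>          ace_mean  genotype      0.68 0.0933     25          25        0
#>  gee_unstructured  genotype      0.68 0.0933     25          25        0
#> Heritability estimates over replicates:
#>    method   mean      sd  n
#>  ace_mean 0.6463 0.06495 25
```

A command-line wrapper over the same functions is installed at
`inst/scripts/twinlong-cli.R` (`simulate`, `fit`, `evaluate` against a
YAML/JSON config; see `?read_sim_config`).

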