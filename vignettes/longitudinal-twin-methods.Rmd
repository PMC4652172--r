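---
title: "Comparing methods for genetic effects on longitudinal twin phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing methods for genetic effects on longitudinal twin phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinlong)
```

## The problem

Longitudinal family studies carry two sources of correlation at once:
repeated measurements on the same child over time, and shared genes and
environment between family members. No standard software models both
exactly, so analysts simplify one of them. `twinlong` is a simulation
laboratory for asking what those simplifications cost when the goal is to
detect a genetic main effect or a gene-by-age interaction on a growth
phenotype (we use BMI in kg/m², measured six times in infancy and early
childhood) in a cohort of monozygotic (MZ) and dizygotic (DZ) twin pairs.

Three families of analyses are implemented around a common generator:

1. **Summary-statistic analyses** — collapse each child's trajectory to a
   mean, an OLS slope/intercept on age, or a trapezoidal area under the
   curve, then fit either the classical twin ACE model (`fit_ace()`) or a
   family random-intercept LMM (`fit_family_lmm()`) with sex and genotype
   as covariates.
2. **Longitudinal analyses with simplified familial correlation** — a
   marginal Gaussian GEE with exchangeable, AR-1, or unstructured working
   correlation and robust sandwich variances (`fit_gee()`), and a
   three-level hierarchical LMM (pair intercept, individual
   intercept+slope, residual; `fit_three_level()`).
3. **A Bayesian variance-components analysis with simplified temporal
   correlation** — all time points enter, but the between-time correlation
   is attributed entirely to the twin-structured random intercepts and
   slopes (`run_mcmc()`, single-site Gibbs via JAGS, flat priors).

`run_replicates()` wraps simulation and analysis into a replicate study
reporting power/type I error, bias, SD of the estimates, and heritability
recovery.

## The generative model

For twin $j$ of pair $i$ at visit $k$,

$$Y_{ijk} = (\beta_0 + \beta_{0ij}) + \beta_S S_{ij} + \beta_G G_{ij}
  + (\beta_T + \beta_{Tij})\,T_{ijk} + \beta_{T'}\,T'_{ijk}
  + \beta_{GT}\,G_{ij} T_{ijk} + \varepsilon_{ijk},
  \qquad \varepsilon_{ijk} \sim N(0, \sigma^2_E)\ \text{i.i.d.}$$

with sex $S_{ij} \in \{0,1\}$, additive genotype $G_{ij} \in \{0,1,2\}$,
age $T_{ijk}$ in months, and a segmented age $T'_{ijk}$ that is 0 for the
first two visits and $T_{ijk} - 6$ afterwards: growth is allowed a slope
change at a 6-month knot (catch-up growth after birth). The random
intercepts have the classical twin covariance structure — variance
$\sigma^2_A + \sigma^2_C$, within-pair covariance $\sigma^2_A + \sigma^2_C$
for MZ and $\tfrac12\sigma^2_A + \sigma^2_C$ for DZ pairs — and the random
age slopes the analogous structure with $\tau^2_A, \tau^2_C$. Intercept
and slope effects are independent. Genotypes come from Hardy–Weinberg
parents (minor allele frequency 0.3) by Mendelian transmission, with the
MZ co-twin receiving a copy of the first twin's genotype.

`sim_model()` provides nine presets spanning no genetic effect (model
"1", the null used for type I error), an effect on the average phenotype
("2a"–"2d", $\beta_G$ from 0.1 to 0.3), a linear effect on the rate of
change ("3a"–"3b", $\beta_{GT}$ 0.005 and 0.01 per allele per month), and
a segmented effect on change ("4a"–"4b"). Every preset implies
single-occasion heritability
$\sigma^2_A/(\sigma^2_A+\sigma^2_C+\sigma^2_E) = 0.5$.

```{r presets}
sim_model("2d")
```

### Design choices in the generator

* **Visit schedule.** The emulated cohort's observed ages are not
  published, so the default schedule is fixed at
  $\{1, 6, 18, 30, 48, 60\}$ months: two visits at or before the 6-month
  knot (required by the segmented-age definition) and follow-up to five
  years, the scale on which a slope of $\beta_T = 0.04$/month is
  meaningful. `build_design()` also accepts per-visit age pools, from
  which each child's ages are drawn independently and sorted — emulating
  designs where observed visit ages vary between children.
* **Cohort size.** 226 DZ + 168 MZ pairs (788 children), the size of the
  motivating twin cohort; configurable.
* **Sex.** Coded 0/1 with probability one half, per pair for MZ twins
  (always concordant), per twin for DZ pairs; the true cohort's sex split
  is not published.
* **Seeding.** One master seed expands into independent substreams for
  design, genotypes, random effects and residuals, so any component can
  be regenerated alone and whole tables reproduce byte-for-byte.

## A consequence of averaging worth knowing about

The mean-over-visits summary divides the occasion-level residual by the
number of visits: under model "1" the mean phenotype has
$\mathrm{Var} = \sigma^2_A + \sigma^2_C + \sigma^2_E/6 = 7.125$, MZ
covariance $6.75$ and DZ covariance $4.5$. The ACE decomposition of those
moments is $\hat\sigma^2_A = 4.5$, $\hat\sigma^2_C = 2.25$,
$\hat\sigma^2_E \approx 0.375$, so the heritability *of the mean
phenotype* is $4.5/7.125 \approx 0.63$ — larger than the single-occasion
value of 0.5, because averaging removes occasion noise while leaving the
familial components untouched. Replicate studies with this package
reproduce exactly that: heritability estimated from the mean summary
concentrates near 0.63, not 0.5. Any analysis that reports "heritability"
from a summary phenotype is reporting the heritability of that summary,
which is design-dependent (it depends on the number of visits); this is a
point to keep in mind when comparing against single-occasion targets.

## The analysis methods and their knobs

**Twin ACE model** (`fit_ace()`): per-pair bivariate normal likelihood
with mean $x'\beta$ (intercept, sex, genotype), common variance
$a^2+c^2+e^2$, covariance $a^2+c^2$ (MZ) or $\tfrac12 a^2+c^2$ (DZ).
Estimation is maximum likelihood in the path-coefficient
parameterization, which enforces non-negative variance components by
squaring. We use ML rather than REML so log-likelihoods are comparable
across methods. Optimization is multi-start (Nelder–Mead then BFGS from
moment-based and dispersed starting values, three starts by default) to
guard against boundary local optima; standard errors come from the
observed information at the optimum, with a generalized inverse as
fallback when a variance sits on the boundary. The genotype test is a
Wald $z$ against the standard normal — the reference twin-model software
does not document its test, and the Wald choice keeps all frequentist
methods on the same decision rule.

**Family LMM** (`fit_family_lmm()`): one random intercept per pair,
zygosity deliberately ignored — this *is* the familial simplification
being studied.

**Three-level hierarchical model** (`fit_three_level()`): random pair
intercept, random individual intercept and age slope with an unstructured
2×2 covariance, independent residual; fixed effects sex, genotype, age,
and optionally genotype×age. Fit by ML with lme4. The individual-level
layout is not uniquely pinned down by the description it follows; we
chose the unstructured intercept+slope pair (no family-level slope)
because it matches "three levels" with a time trend at the child level.
Boundary fits (the generating slope variances can be zero) are reported
through the `singular` flag, not hidden.

**Marginal GEE** (`fit_gee()`): Gaussian identity-link estimating
equations iterating weighted least squares with moment re-estimation of
the working correlation, to relative coefficient change $10^{-8}$ or 100
iterations. Working structures: exchangeable, AR-1 (lag on the visit
index, since visits are unequally spaced in age), unstructured, and fixed
independence (in which case the coefficients equal stacked OLS). The
default cluster is the *individual* (six repeated measures), so the
between-twin correlation is ignored — the familial simplification again;
`cluster = "pair"` is available for sensitivity analysis. Variances are
robust sandwich estimates; an implementation detail worth recording is
that unstructured moment estimators use the $(K-p)$ denominator, so small
differences from other GEE software in the third decimal are expected.

**Bayesian variance components** (`run_mcmc()`): the longitudinal twin
model with all time points and the twin covariance constraints, priors
$N(0, 10^6)$ on fixed effects and $\mathrm{Uniform}(0,100)$ on the five
variance components, sampled by single-site Gibbs (JAGS) using the latent
pair/individual parameterization (MZ: one shared pair effect; DZ: pair
effect plus per-twin individual effects), which is equivalent to the
direct MZ/DZ covariance formulation — the equivalence is checked in the
test suite — and mixes better under component-wise updates. Default
schedule: three chains of 10,000 iterations, 1000 burn-in. The decision
rule is exclusion of 0 from the central 95% credible interval
(`credible_decision()`). Component-wise sampling on this model mixes
slowly for parameters that compete for the same variance; at full cohort
size the variance components are the well-known weak spot, and on small
test datasets the global intercept and genotype effect can be the slowest
movers instead. `convergence_report()` exposes effective sample sizes and
scale-reduction factors and flags poorly mixing parameters; variance
components from this sampler should be treated as qualitative. Fixed
effects, by contrast, agree closely with the ML longitudinal fit, and the
prior-sensitivity harness (`prior_sensitivity()`) lets you verify that
tightening the fixed-effect prior to variance 100–500 or narrowing the
uniform ranges leaves them essentially unchanged. Uniform ranges
extending below zero are clipped at zero: a variance prior cannot give
mass to negative values in a precision-based sampler.

## The replicate harness

`run_replicates()` derives one sub-seed per replicate from the master
seed, simulates a fresh cohort, fits every requested method *to the same
data* (common random numbers keep between-method comparisons tight), and
records the decision on the genotype effect — or on genotype×age for
longitudinal methods when the generating model has an interaction
(segmented generating models "4a"/"4b" are analysed with the linear-time
specification, so their interaction is tested against a slightly
misspecified mean model, deliberately). Method failures in a replicate
are caught, logged in the report and excluded; they never abort a study.
`power_curve()` sweeps generating models for one method;
`estimate_table()` formats the mean (SD) grid over replicates. The
Bayesian method can be restricted to a subset of replicates
(`bayes_reps`) because of its cost, and is then reported with its own
replicate count.

Default problem sizes in the shipped tests and acceptance script are
desk-scale choices: 200 replicates for estimate-recovery and
heritability summaries, 300–500 for type I error, against the 2000 a
full study would use; Monte Carlo standard errors are reported with every
proportion so the bands, not point equality, are what the tests assert.

## What the simulations do and do not emulate

The generator reproduces the statistical skeleton of a real twin growth
cohort: its twin-pair structure, complete six-visit trajectories, a
segmented mean trajectory, twin-structured random effects calibrated to
realistic BMI variance components, and a common SNP under Mendelian
transmission. It does *not* emulate missing visits or dropout (complete
data by design), more than one SNP or any linkage disequilibrium,
parental phenotypes, measurement error models beyond Gaussian residuals,
or secular/seasonal effects. Passing tests therefore demonstrate method
behaviour under a clean, correctly specified growth process — real
cohorts add irregular spacing and missingness that generally *widen* the
gaps between methods, not close them.

## Empirically notable behaviours

Two behaviours of the methods under this generator deserve flagging, and
both are computed (not asserted) by the shipped replicate studies:

* Methods that ignore or pool the familial correlation when testing a
  between-family covariate are anti-conservative here. The
  individual-clustered GEE ignores the twin correlation entirely, and its
  null rejection rate at the 5% level lands above nominal by roughly a
  factor of two. The three-level hierarchical model pools MZ and DZ pairs
  into a single exchangeable pair variance; because MZ genotypes are
  fully shared within pairs while their phenotypic correlation is higher
  than the pooled estimate assumes, its genotype SE is also somewhat
  underestimated and the null test rejects at roughly twice nominal as
  well. The twin ACE model, which models zygosity, stays at nominal.
* Estimation of the genetic effects themselves is close to unbiased for
  the correctly targeted method-summary combinations: the mean-summary
  ACE recovers a mean effect of 0.3 per allele; the three-level model
  recovers an interaction of 0.005 per allele-month; and the
  slope-summary ACE captures an interaction of 0.01 as its genotype main
  effect.

## Limitations

* The ACE model here is exactly ACE: no dominance, no sex-limitation, no
  bivariate extensions.
* The GEE implementation assumes complete, equally sized clusters
  (guaranteed by the generator) and Gaussian working variance; no
  small-sample sandwich corrections are applied.
* The Bayesian sampler inherits the mixing pathologies of single-site
  updates on variance-component models; its variance posteriors are
  diagnostic output, not inferential targets.
* The acceptance surface runs at reduced replicate counts; Monte Carlo
  bands are quoted with every number for exactly that reason.
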