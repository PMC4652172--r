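# Small-scale MCMC checks: prior recovery through the sampling hook,
# decision-rule logic, diagnostics, and posterior agreement with the
# frequentist longitudinal fit on a modest dataset.

test_that("prior-only sampling recovers the flat priors", {
  post <- run_mcmc(NULL, n_iter = 4000, burn_in = 500, chains = 2, seed = 41,
                   sample_prior = TRUE)
  s <- post$summary
  v <- s[s$parameter == "sigmaA2", ]
  n_draws <- 2 * 3500
  expect_lt(abs(v$mean - 50), 3 * (100 / sqrt(12)) / sqrt(n_draws) * 2)
  draws <- as.matrix(post$samples)[, "sigmaA2"]
  expect_gte(min(draws), 0)
  expect_lte(max(draws), 100)
  ks <- suppressWarnings(ks.test(draws, "punif", 0, 100))
  expect_gt(ks$p.value, 0.001)
  # symmetric flat normal prior on a fixed effect straddles zero
  expect_false(credible_decision(post, "betaG"))
  # a positive-support uniform prior excludes zero by construction
  expect_true(credible_decision(post, "sigmaE2"))
  expect_error(credible_decision(post, "not_a_parameter"), "unknown parameter")
})

test_that("prior overrides are respected and negative ranges clipped", {
  expect_warning(p <- prior_spec(var_range_overrides = list(sigmaA2 = c(-10, 10))),
                 "clipped")
  expect_equal(p$var_range$sigmaA2, c(0, 10))
  p2 <- prior_spec(fixed_var = 500, fixed_var_overrides = list(betaG = 100))
  expect_equal(unname(p2$fixed_var[["betaG"]]), 100)
  expect_equal(unname(p2$fixed_var[["beta0"]]), 500)
  post <- run_mcmc(NULL, priors = p2, n_iter = 3000, burn_in = 500,
                   chains = 1, seed = 42, sample_prior = TRUE)
  draws <- as.matrix(post$samples)[, "betaG"]
  expect_lt(abs(sd(draws) - 10), 1)
})

test_that("convergence diagnostics behave on synthetic chains", {
  set.seed(43)
  mk <- function() coda::mcmc(matrix(rnorm(4000), ncol = 2,
                                     dimnames = list(NULL, c("a", "b"))))
  rep1 <- convergence_report(coda::mcmc.list(mk(), mk()))
  expect_lt(max(rep1$rhat), 1.05)  # well-mixed chains: scale reduction ~ 1
  iid <- coda::mcmc.list(coda::mcmc(matrix(rnorm(4000), ncol = 2,
                                           dimnames = list(NULL, c("a", "b")))))
  rep2 <- convergence_report(iid)
  expect_gt(min(rep2$ess), 0.5 * 2000)
  expect_lt(max(rep2$ess), 2 * 2000)
  expect_false(any(rep2$poor_mixing))
})

test_that("posterior fixed effects agree with the frequentist longitudinal fit", {
  dat <- simulate_twin_data(sim_model("2d"), n_dz = 35, n_mz = 25, seed = 109)
  post <- run_mcmc(dat, n_iter = 4000, burn_in = 500, chains = 1, seed = 44,
                   include_gxt = FALSE)
  freq <- fit_three_level(dat)
  fe <- setNames(freq$coefficients$estimate, freq$coefficients$term)
  se <- setNames(freq$coefficients$se, freq$coefficients$term)
  s <- post$summary
  pick <- function(p) s$mean[s$parameter == p]
  expect_lt(abs(pick("beta0") - fe[["(Intercept)"]]), 3 * se[["(Intercept)"]])
  expect_lt(abs(pick("betaS") - fe[["sex"]]), 3 * se[["sex"]])
  expect_lt(abs(pick("betaG") - fe[["genotype"]]), 3 * se[["genotype"]])
  expect_lt(abs(pick("betaT") - fe[["age_months"]]), 3 * se[["age_months"]])
  # the generating genotype effect lies inside its own 95% interval
  expect_gt(0.3, s$q2.5[s$parameter == "betaG"])
  expect_lt(0.3, s$q97.5[s$parameter == "betaG"])
  # diagnostics cover every parameter and flag low-ESS ones consistently
  cr <- convergence_report(post, ess_frac = 0.1)
  expect_setequal(cr$parameter, s$parameter)
  total <- 3500
  expect_equal(cr$poor_mixing, cr$ess < 0.1 * total)
  expect_true(any(cr$poor_mixing))  # single-site updates do mix poorly here
  # per-draw heritability is carried as a derived parameter in (0, 1)
  h2 <- as.matrix(post$samples)[, "h2"]
  expect_true(all(h2 >= 0 & h2 <= 1))
})

test_that("degenerate phenotypes are rejected before sampling", {
  dat <- simulate_twin_data(sim_model("1"), n_dz = 4, n_mz = 4, seed = 45)
  dat$bmi <- 12
  expect_error(run_mcmc(dat, n_iter = 200, burn_in = 50, chains = 1, seed = 1),
               "zero variance")
})
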