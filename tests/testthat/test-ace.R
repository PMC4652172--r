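ace_test_data <- function(model = "1", n_dz = 60, n_mz = 40, seed = 1,
                          response = "mean") {
  dat <- simulate_twin_data(sim_model(model), n_dz = n_dz, n_mz = n_mz,
                            seed = seed)
  summarize_trajectories(dat, response)
}

test_that("the ACE log-likelihood equals a generic bivariate-normal oracle", {
  s <- ace_test_data(seed = 3)
  set.seed(7)
  for (trial in 1:4) {
    beta <- c(rnorm(1, 12, 1), rnorm(2, 0, 0.3))
    a <- runif(1, 0.5, 3); cc <- runif(1, 0.1, 2); e <- runif(1, 0.3, 2)
    ll <- ace_loglik(s, beta, a, cc, e)
    # oracle: per-pair 2x2 multivariate normal density via matrix algebra
    X <- cbind(1, s$sex, s$genotype)
    mu <- drop(X %*% beta)
    v <- a^2 + cc^2 + e^2
    oracle <- 0
    for (pid in unique(s$pair_id)) {
      i <- which(s$pair_id == pid)
      cv <- if (s$zygosity[i[1]] == "MZ") a^2 + cc^2 else 0.5 * a^2 + cc^2
      S <- matrix(c(v, cv, cv, v), 2)
      oracle <- oracle + mvn_logdens(s$mean[i], mu[i], S)
    }
    expect_equal(ll, oracle, tolerance = 1e-10)
  }
})

test_that("without familial components the likelihood is a product of normals", {
  s <- ace_test_data(seed = 4)
  beta <- c(12, 0.4, 0.1)
  ll <- ace_loglik(s, beta, a = 0, c = 0, e = 1.5)
  mu <- drop(cbind(1, s$sex, s$genotype) %*% beta)
  expect_equal(ll, sum(dnorm(s$mean, mu, 1.5, log = TRUE)), tolerance = 1e-10)
})

test_that("the likelihood is exchangeable in twin order and rejects a=c=e=0", {
  s <- ace_test_data(seed = 5)
  swapped <- s
  swapped$twin <- 3L - swapped$twin
  beta <- c(12, 0.4, 0.1)
  expect_equal(ace_loglik(s, beta, 1.5, 1, 0.8),
               ace_loglik(swapped, beta, 1.5, 1, 0.8), tolerance = 1e-12)
  expect_error(ace_loglik(s, beta, 0, 0, 0), "singular")
})

test_that("maximum likelihood dominates the generating parameters", {
  truth_beta <- c(11 + 0, 0.5, 0)  # mean-phenotype fixed effects under model 1
  for (seed in 1:3) {
    s <- ace_test_data(seed = seed, n_dz = 80, n_mz = 60)
    fit <- fit_ace(s, "mean")
    expect_true(fit$converged)
    # residual of the mean phenotype: sigmaE2 / 6 visits
    ll_truth <- ace_loglik(s, truth_beta, sqrt(4.5), sqrt(2.25), sqrt(2.25 / 6))
    expect_gte(fit$logLik, ll_truth - 1e-6)
  }
})

test_that("a generator without familial correlation drives a2 and c2 to zero", {
  p <- twin_params(sigmaA2 = 0, sigmaC2 = 0, sigmaE2 = 4)
  dat <- simulate_twin_data(p, n_dz = 250, n_mz = 150, seed = 6)
  fit <- fit_ace(summarize_trajectories(dat, "mean"), "mean")
  expect_lt((fit$varcomp[["sigmaA2"]] + fit$varcomp[["sigmaC2"]]) /
              sum(fit$varcomp), 0.25)
})

test_that("heritability of a fit is the additive share and stays in [0, 1]", {
  s <- ace_test_data(seed = 8)
  fit <- fit_ace(s, "mean")
  expect_identical(heritability(fit), fit$h2)
  expect_gte(fit$h2, 0)
  expect_lte(fit$h2, 1)
  expect_true(all(fit$varcomp >= 0))
})

test_that("incomplete pairs are rejected", {
  s <- ace_test_data(seed = 9)
  expect_error(fit_ace(s[-1, ], "mean"), "complete pairs")
})
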