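test_that("family LMM fixed effects equal the GLS solution at the fitted variances", {
  dat <- simulate_twin_data(sim_model("2d"), n_dz = 80, n_mz = 60, seed = 21)
  s <- summarize_trajectories(dat, "mean")
  fit <- fit_family_lmm(s, "mean")
  # GLS oracle: per-pair covariance sigma_p^2 J + sigma_r^2 I
  sp <- fit$varcomp[["pair"]]; sr <- fit$varcomp[["residual"]]
  Sinv <- solve(matrix(sp, 2, 2) + diag(sr, 2))
  X <- cbind(1, s$sex, s$genotype)
  A <- matrix(0, 3, 3); b <- rep(0, 3)
  for (pid in unique(s$pair_id)) {
    i <- which(s$pair_id == pid)
    Xi <- X[i, ]; yi <- s$mean[i]
    A <- A + t(Xi) %*% Sinv %*% Xi
    b <- b + t(Xi) %*% Sinv %*% yi
  }
  expect_equal(fit$coefficients$estimate, solve(A, b)[, 1], tolerance = 1e-6)
})

test_that("zero between-family variance is recovered at the boundary", {
  p <- twin_params(sigmaA2 = 0, sigmaC2 = 0, sigmaE2 = 3)
  dat <- simulate_twin_data(p, n_dz = 200, n_mz = 150, seed = 22)
  fit <- fit_family_lmm(summarize_trajectories(dat, "mean"), "mean")
  expect_lt(fit$varcomp[["pair"]] / sum(fit$varcomp), 0.1)
})

test_that("the three-level model recovers fixed effects in the noise-free limit", {
  p <- twin_params(betaG = 0.25, betaGT = 0.004, sigmaA2 = 0, sigmaC2 = 0,
                   sigmaE2 = 1e-6, tauA2 = 0, tauC2 = 0)
  dat <- simulate_twin_data(p, n_dz = 30, n_mz = 20, seed = 23)
  fit <- fit_three_level(dat, include_gxt = TRUE)
  est <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  expect_equal(est[["(Intercept)"]], 11, tolerance = 1e-3)
  expect_equal(est[["sex"]], 0.5, tolerance = 1e-3)
  expect_equal(est[["genotype"]], 0.25, tolerance = 1e-3)
  expect_equal(est[["age_months"]], 0.04, tolerance = 1e-3)
  expect_equal(est[["genotype:age_months"]], 0.004, tolerance = 1e-3)
})

test_that("the three-level ML log-likelihood matches a 12x12 per-family oracle", {
  dat <- simulate_twin_data(sim_model("3a"), n_dz = 40, n_mz = 30, seed = 24)
  fit <- fit_three_level(dat, include_gxt = TRUE)
  vc <- fit$varcomp
  est <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  ages <- c(1, 6, 18, 30, 48, 60)
  Sfam <- family_cov_oracle(vc, ages)
  ll <- 0
  for (pid in unique(dat$pair_id)) {
    sub <- dat[dat$pair_id == pid, ]
    sub <- sub[order(sub$twin, sub$visit), ]
    mu <- est[["(Intercept)"]] + est[["sex"]] * sub$sex +
      est[["genotype"]] * sub$genotype + est[["age_months"]] * sub$age_months +
      est[["genotype:age_months"]] * sub$genotype * sub$age_months
    ll <- ll + mvn_logdens(sub$bmi, mu, Sfam)
  }
  expect_equal(fit$logLik, ll, tolerance = 1e-6)
})

test_that("marginal (pair-clustered GEE) and hierarchical estimates agree at large n", {
  dat <- simulate_twin_data(sim_model("2d"), n_dz = 700, n_mz = 500, seed = 25)
  hier <- fit_three_level(dat)
  gee <- fit_gee(dat, "unstructured", cluster = "pair")
  eh <- setNames(hier$coefficients$estimate, hier$coefficients$term)
  eg <- setNames(gee$coefficients$estimate, gee$coefficients$term)
  for (term in c("sex", "genotype", "age_months")) {
    expect_lt(abs(eh[[term]] - eg[[term]]), 0.06)
  }
})

test_that("a singular random-effects covariance is reported, not hidden", {
  dat <- simulate_twin_data(sim_model("1"), n_dz = 40, n_mz = 30, seed = 26)
  fit <- fit_three_level(dat)   # generating slope variances are zero
  expect_true(is.logical(fit$singular))
  expect_true(all(c("pair", "ind_intercept", "ind_slope", "residual")
                  %in% names(fit$varcomp)))
})
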