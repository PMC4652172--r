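noise_free <- function(betaS = 0.5, betaG = 0, betaT = 0.04, betaTprime = 0,
                       betaGT = 0) {
  twin_params(beta0 = 11, betaS = betaS, betaG = betaG, betaT = betaT,
              betaTprime = betaTprime, betaGT = betaGT,
              sigmaA2 = 0, sigmaC2 = 0, sigmaE2 = 0, tauA2 = 0, tauC2 = 0)
}

test_that("the deterministic limit reproduces the fixed-effect arithmetic", {
  d <- build_design(1, 0, visit_ages = c(1, 6, 10, 30, 48, 60), seed = 1)
  d$sex <- rep(c(0L, 1L), each = 6)  # twin 1 female-coded 0, twin 2 coded 1
  g <- simulate_genotypes(d, maf = 0, seed = 1)
  y <- simulate_phenotypes(d, g, noise_free(), seed = 1)
  # beta0 + betaT * age at age 10 for sex 0; + betaS for sex 1
  expect_equal(y$bmi[y$twin == 1 & y$age_months == 10], 11 + 0.4)
  expect_equal(y$bmi[y$twin == 2 & y$age_months == 10], 11 + 0.5 + 0.4)
})

test_that("the segmented slope cancels a matched negative post-knot effect", {
  # betaT = 0.8, betaT' = -0.8: no net change between 6 and 12 months
  d <- build_design(1, 0, visit_ages = c(1, 6, 12, 30, 48, 60), seed = 2)
  g <- simulate_genotypes(d, maf = 0, seed = 2)
  y <- simulate_phenotypes(d, g, noise_free(betaT = 0.8, betaTprime = -0.8),
                           seed = 2)
  y1 <- y[y$twin == 1, ]
  expect_equal(y1$bmi[y1$visit == 3] - y1$bmi[y1$visit == 2], 0)
  # before the knot the full slope applies
  expect_equal(y1$bmi[y1$visit == 2] - y1$bmi[y1$visit == 1], 0.8 * 5)
})

test_that("segmented age is zero for the first two visits and age - knot after", {
  dat <- simulate_twin_data(sim_model("4a"), n_dz = 5, n_mz = 5, seed = 3)
  expect_true(all(dat$age_post_knot[dat$visit <= 2] == 0))
  expect_equal(dat$age_post_knot[dat$visit > 2],
               dat$age_months[dat$visit > 2] - 6)
  expect_equal(sum(table(dat$pair_id) != 12), 0)
  expect_false(anyNA(dat))
})

test_that("marginal variance at a fixed age matches the closed form", {
  # model-1 components without sex/genotype effects: var = sA2 + sC2 + sE2
  p <- twin_params(betaS = 0, sigmaA2 = 4.5, sigmaC2 = 2.25, sigmaE2 = 2.25)
  dat <- simulate_twin_data(p, n_dz = 6000, n_mz = 4000, seed = 4)
  v1 <- var(dat$bmi[dat$visit == 1])
  expect_lt(abs(v1 - 9) / 9, 3 * sqrt(2 / 10000) * 1.5)
  # and with a genotype main effect the genotype variance adds on
  p2 <- twin_params(betaS = 0, betaG = 0.3, sigmaA2 = 4.3, sigmaC2 = 2.25,
                    sigmaE2 = 2.25)
  dat2 <- simulate_twin_data(p2, n_dz = 6000, n_mz = 4000, seed = 5)
  vg <- 2 * 0.3 * 0.7            # Var(G) under Hardy-Weinberg
  expected <- 4.3 + 2.25 + 2.25 + 0.3^2 * vg
  v2 <- var(dat2$bmi[dat2$visit == 1])
  expect_lt(abs(v2 - expected) / expected, 3 * sqrt(2 / 10000) * 1.5)
})

test_that("MZ phenotype correlation exceeds DZ and both match the closed form", {
  p <- twin_params(betaS = 0, sigmaA2 = 4.5, sigmaC2 = 2.25, sigmaE2 = 2.25)
  dat <- simulate_twin_data(p, n_dz = 5000, n_mz = 5000, seed = 77)
  v1 <- dat[dat$visit == 1, ]
  icc <- function(z) {
    w <- v1[v1$zygosity == z, ]
    cor(w$bmi[w$twin == 1], w$bmi[w$twin == 2])
  }
  r_mz <- icc("MZ"); r_dz <- icc("DZ")
  # intra-class correlations implied by the covariance structure
  expect_lt(abs(r_mz - 6.75 / 9), 3 * (1 - 0.75^2) / sqrt(5000))
  expect_lt(abs(r_dz - 4.5 / 9), 3 * (1 - 0.5^2) / sqrt(5000))
  expect_gt(r_mz, r_dz)
})

test_that("simulation is reproducible and round-trips through CSV", {
  a <- simulate_twin_data(sim_model("2d"), n_dz = 8, n_mz = 7, seed = 11)
  b <- simulate_twin_data(sim_model("2d"), n_dz = 8, n_mz = 7, seed = 11)
  expect_identical(a, b)
  f <- tempfile(fileext = ".csv")
  write_twin_csv(a, f)
  back <- read_twin_csv(f)
  expect_equal(as.data.frame(back), as.data.frame(a), tolerance = 1e-12)
  unlink(f)
})

test_that("mismatched design and genotypes are rejected", {
  d <- build_design(4, 4, seed = 1)
  g <- simulate_genotypes(build_design(3, 3, seed = 1), 0.3, seed = 1)
  expect_error(simulate_phenotypes(d, g, sim_model("1"), seed = 1),
               "does not match")
})
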