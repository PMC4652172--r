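test_that("a single-replicate report equals the corresponding direct fit", {
  seed <- 71
  rep <- run_replicates(sim_model("2d"), "ace_mean", n_reps = 1,
                        seed = seed, n_dz = 25, n_mz = 20)
  rep_seed <- twinlong:::derive_seeds(seed, 1, salt = 3L)
  dat <- simulate_twin_data(sim_model("2d"), n_dz = 25, n_mz = 20,
                            seed = rep_seed)
  fit <- fit_ace(summarize_trajectories(dat, "mean"), "mean")
  got <- setNames(rep$estimates$mean, rep$estimates$term)
  expect_equal(got[["genotype"]],
               fit$coefficients$estimate[fit$coefficients$term == "genotype"])
  expect_equal(rep$h2$mean, fit$h2)
  expect_equal(rep$rejection$rejection,
               as.numeric(fit$coefficients$p[fit$coefficients$term == "genotype"]
                          < 0.05))
})

test_that("replicate studies are reproducible from the master seed", {
  a <- run_replicates(sim_model("1"), c("ace_mean", "gee_exchangeable"),
                      n_reps = 3, seed = 5, n_dz = 20, n_mz = 15)
  b <- run_replicates(sim_model("1"), c("ace_mean", "gee_exchangeable"),
                      n_reps = 3, seed = 5, n_dz = 20, n_mz = 15)
  expect_identical(a$results, b$results)
  expect_identical(a$rejection, b$rejection)
})

test_that("longitudinal methods test the interaction when the model has one", {
  rep <- run_replicates(sim_model("3a"), c("hierarchical", "gee_ar1"),
                        n_reps = 1, seed = 6, n_dz = 20, n_mz = 15)
  expect_true(all(rep$rejection$test_term == "genotype:age_months"))
  rep0 <- run_replicates(sim_model("1"), "gee_ar1", n_reps = 1, seed = 6,
                         n_dz = 20, n_mz = 15)
  expect_equal(rep0$rejection$test_term, "genotype")
})

test_that("method failures are logged and excluded, never fatal", {
  local_mocked_bindings(
    fit_one_method = function(...) stop("synthetic failure"),
    .package = "twinlong"
  )
  rep <- run_replicates(sim_model("1"), "ace_mean", n_reps = 2, seed = 7,
                        n_dz = 5, n_mz = 5)
  expect_equal(nrow(rep$failures), 2L)
  expect_match(rep$failures$message[1], "synthetic failure")
  expect_equal(nrow(rep$results), 0L)
})

test_that("unknown methods are rejected up front", {
  expect_error(run_replicates(sim_model("1"), "anova", n_reps = 1, seed = 1),
               "unknown method")
})

test_that("power_curve tabulates one rejection rate per model", {
  models <- list(null = sim_model("1"), effect = sim_model("2d"))
  pc <- power_curve(models, "gee_exchangeable", n_reps = 3, seed = 8,
                    n_dz = 20, n_mz = 15)
  expect_equal(pc$model, c("null", "effect"))
  expect_equal(pc$effect, c(0, 0.3))
  expect_true(all(pc$rejection >= 0 & pc$rejection <= 1))
  expect_true(all(pc$n_used == 3))
})

test_that("estimate_table formats mean (SD) and near-zero SD when noise-free", {
  p <- twin_params(betaG = 0.2, sigmaA2 = 0, sigmaC2 = 0, sigmaE2 = 1e-8)
  rep <- run_replicates(p, "gee_independence", n_reps = 3, seed = 9,
                        n_dz = 15, n_mz = 10)
  tab <- estimate_table(rep)
  expect_true("genotype" %in% names(tab))
  expect_match(tab$genotype[1], "^0\\.2 \\(")
  sds <- rep$estimates$sd[rep$estimates$term == "genotype"]
  expect_lt(max(sds), 1e-3)
})

test_that("configuration files select models and defaults", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("model: 2d", "n_dz: 10", "n_mz: 5", "n_reps: 4", "seed: 3",
               "methods:", "  - ace_mean", "  - hierarchical"), f)
  cfg <- read_sim_config(f)
  expect_equal(cfg$params$betaG, 0.3)
  expect_equal(cfg$n_dz, 10)
  expect_equal(cfg$methods, c("ace_mean", "hierarchical"))
  unlink(f)
  g <- tempfile(fileext = ".json")
  writeLines('{"params": {"betaG": 0.12, "sigmaA2": 1, "sigmaC2": 1, "sigmaE2": 1}, "seed": 2}', g)
  cfg2 <- read_sim_config(g)
  expect_equal(cfg2$params$betaG, 0.12)
  expect_equal(cfg2$n_dz, 226L)
  unlink(g)
  expect_error(read_sim_config(tempfile()), "not found")
})
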