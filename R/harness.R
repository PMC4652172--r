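# Replicate harness: simulate -> fit every requested method -> aggregate
# power / type I error, bias and SD of estimates, heritability recovery.

.methods <- c("ace_mean", "ace_slope", "ace_intercept", "ace_auc",
              "lmm_mean", "lmm_slope", "lmm_intercept", "lmm_auc",
              "gee_exchangeable", "gee_ar1", "gee_unstructured",
              "gee_independence", "hierarchical", "bayes")

# Fit one method to one dataset; returns a uniform record:
# coefficients data frame, the tested term, its p-value / decision,
# variance components / h2 where produced, convergence flag.
fit_one_method <- function(method, data, include_gxt, control = list()) {
  summary_stat <- sub("^(ace|lmm)_", "", method)
  if (grepl("^ace_", method)) {
    summ <- summarize_trajectories(data, summary_stat)
    fit <- fit_ace(summ, response = summary_stat)
    co <- fit$coefficients
    list(coefficients = co, test_term = "genotype",
         p = co$p[co$term == "genotype"],
         h2 = fit$h2, varcomp = fit$varcomp, converged = fit$converged)
  } else if (grepl("^lmm_", method)) {
    summ <- summarize_trajectories(data, summary_stat)
    fit <- fit_family_lmm(summ, response = summary_stat)
    co <- fit$coefficients
    list(coefficients = co, test_term = "genotype",
         p = co$p[co$term == "genotype"],
         h2 = NA_real_, varcomp = fit$varcomp, converged = fit$converged)
  } else if (grepl("^gee_", method)) {
    structure <- sub("^gee_", "", method)
    cluster <- control$gee_cluster %||% "individual"
    fit <- fit_gee(data, structure = structure, cluster = cluster,
                   include_gxt = include_gxt)
    term <- if (include_gxt) "genotype:age_months" else "genotype"
    co <- fit$coefficients
    list(coefficients = co, test_term = term, p = co$p[co$term == term],
         h2 = NA_real_, varcomp = NULL, converged = fit$converged)
  } else if (method == "hierarchical") {
    fit <- fit_three_level(data, include_gxt = include_gxt)
    term <- if (include_gxt) "genotype:age_months" else "genotype"
    co <- fit$coefficients
    list(coefficients = co, test_term = term, p = co$p[co$term == term],
         h2 = NA_real_, varcomp = fit$varcomp, converged = fit$converged)
  } else if (method == "bayes") {
    bc <- control$bayes %||% list()
    fit <- run_mcmc(data,
                    n_iter = bc$n_iter %||% 10000L,
                    burn_in = bc$burn_in %||% 1000L,
                    chains = bc$chains %||% 1L,
                    seed = bc$seed %||% 1L,
                    include_gxt = include_gxt)
    term <- if (include_gxt) "betaGT" else "betaG"
    s <- fit$summary
    co <- data.frame(term = s$parameter, estimate = s$mean,
                     se = NA_real_, z = NA_real_, p = NA_real_,
                     stringsAsFactors = FALSE)
    h2 <- s$mean[s$parameter == "h2"]
    list(coefficients = co, test_term = term,
         decision = credible_decision(fit, term),
         p = NA_real_, h2 = h2, varcomp = NULL, converged = TRUE)
  } else {
    stop("unknown method ", deparse(method), "; available: ",
         paste(.methods, collapse = ", "), call. = FALSE)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a replicate simulation study
#'
#' For each replicate a fresh twin cohort is simulated under `params`,
#' every requested method is fitted to the *same* dataset (common random
#' numbers, so method comparisons are paired), and the test decision on
#' the genotype effect — or the genotype-by-age effect for longitudinal
#' methods when the generating model has one — is recorded. Aggregates
#' are the mean and SD of each estimated coefficient, the rejection
#' proportion at level `alpha` (credible-interval exclusion for the
#' Bayesian method) with its Monte Carlo standard error, heritability
#' summaries where produced, and the non-convergence/failure count. A
#' method failure in a replicate is logged and excluded, never fatal.
#'
#' Methods: `"ace_mean"`, `"ace_slope"`, `"ace_intercept"`, `"ace_auc"`
#' (classical twin ACE on a summary), `"lmm_*"` (family random-intercept
#' model on a summary), `"gee_exchangeable"`, `"gee_ar1"`,
#' `"gee_unstructured"`, `"gee_independence"`, `"hierarchical"`
#' (three-level model), `"bayes"`.
#'
#' @param params a [twin_params()] object (e.g. from [sim_model()]).
#' @param methods character vector of method names.
#' @param n_reps number of replicates.
#' @param seed master seed; replicate seeds are derived from it.
#' @param n_dz,n_mz,visit_ages,knot passed to [simulate_twin_data()].
#' @param alpha two-sided test level.
#' @param include_gxt whether longitudinal methods model genotype-by-age;
#'   default: yes iff the generating `betaGT` is non-zero (segmented
#'   generating models are analysed with the linear-time specification).
#' @param gee_cluster cluster definition for GEE methods.
#' @param bayes_control list(n_iter, burn_in, chains) for the Bayesian
#'   method.
#' @param bayes_reps run the (costly) Bayesian method on only the first
#'   `bayes_reps` replicates; it is reported with its own replicate count.
#' @param progress print a dot per replicate.
#' @return An object of class `twin_eval`: `results` (one row per
#'   replicate x method x coefficient), `rejection` (per method: tested
#'   term, rejection proportion, Monte Carlo SE, replicate counts),
#'   `estimates` (per method x term: mean, SD over replicates),
#'   `h2` (per method where available: mean, SD), and the settings.
#' @export
#' @examples
#' rep <- run_replicates(sim_model("2d"), "ace_mean", n_reps = 3,
#'                       seed = 1, n_dz = 20, n_mz = 15)
#' rep$rejection
run_replicates <- function(params, methods, n_reps, seed = 1,
                           n_dz = 226, n_mz = 168,
                           visit_ages = c(1, 6, 18, 30, 48, 60), knot = 6,
                           alpha = 0.05, include_gxt = NULL,
                           gee_cluster = "individual",
                           bayes_control = list(n_iter = 4000L,
                                                burn_in = 500L, chains = 1L),
                           bayes_reps = NULL, progress = FALSE) {
  stopifnot(inherits(params, "twin_params"), n_reps >= 1L,
            length(methods) >= 1L)
  bad <- setdiff(methods, .methods)
  if (length(bad)) stop("unknown method(s): ", paste(bad, collapse = ", "),
                        "; available: ", paste(.methods, collapse = ", "),
                        call. = FALSE)
  if (is.null(include_gxt)) include_gxt <- params$betaGT != 0
  rep_seeds <- derive_seeds(seed, n_reps, salt = 3L)
  if (is.null(bayes_reps)) bayes_reps <- n_reps

  rows <- vector("list", n_reps * length(methods))
  fails <- list()
  ri <- 0L
  for (r in seq_len(n_reps)) {
    dat <- simulate_twin_data(params, n_dz = n_dz, n_mz = n_mz,
                              visit_ages = visit_ages, knot = knot,
                              seed = rep_seeds[r])
    for (m in methods) {
      if (m == "bayes" && r > bayes_reps) next
      control <- list(gee_cluster = gee_cluster,
                      bayes = c(bayes_control,
                                list(seed = rep_seeds[r] %% 100000L + 1L)))
      res <- tryCatch(fit_one_method(m, dat, include_gxt, control),
                      error = function(e) e)
      if (inherits(res, "error")) {
        fails[[length(fails) + 1L]] <-
          data.frame(rep = r, method = m, message = conditionMessage(res),
                     stringsAsFactors = FALSE)
        next
      }
      reject <- if (m == "bayes") res$decision else res$p < alpha
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        rep = r, method = m,
        term = res$coefficients$term,
        estimate = res$coefficients$estimate,
        test_term = res$test_term,
        reject = reject,
        h2 = res$h2 %||% NA_real_,
        converged = res$converged,
        stringsAsFactors = FALSE
      )
    }
    if (progress) cat(".", if (r %% 50L == 0L) paste0(" ", r, "\n"))
  }
  results <- if (ri > 0L) do.call(rbind, rows[seq_len(ri)]) else
    data.frame(rep = integer(), method = character(), term = character(),
               estimate = numeric(), test_term = character(),
               reject = logical(), h2 = numeric(), converged = logical(),
               stringsAsFactors = FALSE)
  failures <- if (length(fails)) do.call(rbind, fails) else
    data.frame(rep = integer(), method = character(), message = character())

  one_per_fit <- results[!duplicated(results[, c("rep", "method")]), ]
  rejection <- if (nrow(results) == 0L) {
    data.frame(method = character(), test_term = character(),
               rejection = numeric(), mc_se = numeric(),
               n_used = integer(), n_requested = integer(),
               n_failed = integer(), n_nonconverged = integer())
  } else do.call(rbind, lapply(unique(results$method), function(m) {
    sub <- one_per_fit[one_per_fit$method == m, ]
    prop <- mean(sub$reject)
    data.frame(method = m, test_term = sub$test_term[1L],
               rejection = prop, mc_se = mc_se_prop(prop, nrow(sub)),
               n_used = nrow(sub),
               n_requested = if (m == "bayes") min(bayes_reps, n_reps)
                             else n_reps,
               n_failed = sum(failures$method == m),
               n_nonconverged = sum(!sub$converged),
               stringsAsFactors = FALSE)
  }))
  estimates <- if (nrow(results) == 0L) {
    data.frame(method = character(), term = character(), mean = numeric(),
               sd = numeric(), n = integer())
  } else {
    agg <- stats::aggregate(estimate ~ method + term, data = results,
                            function(v) c(mean = mean(v), sd = stats::sd(v),
                                          n = length(v)))
    data.frame(method = agg$method, term = agg$term,
               mean = agg$estimate[, "mean"],
               sd = agg$estimate[, "sd"],
               n = agg$estimate[, "n"],
               stringsAsFactors = FALSE)
  }
  h2sub <- one_per_fit[!is.na(one_per_fit$h2), ]
  h2 <- if (nrow(h2sub)) {
    do.call(rbind, lapply(unique(h2sub$method), function(m) {
      v <- h2sub$h2[h2sub$method == m]
      data.frame(method = m, mean = mean(v), sd = stats::sd(v),
                 n = length(v), stringsAsFactors = FALSE)
    }))
  } else NULL

  out <- list(results = results, rejection = rejection,
              estimates = estimates, h2 = h2, failures = failures,
              settings = list(params = params, methods = methods,
                              n_reps = n_reps, seed = seed, n_dz = n_dz,
                              n_mz = n_mz, alpha = alpha,
                              include_gxt = include_gxt,
                              gee_cluster = gee_cluster))
  class(out) <- "twin_eval"
  out
}

#' @export
print.twin_eval <- function(x, ...) {
  cat("Replicate evaluation:", x$settings$n_reps, "replicates,",
      x$settings$n_dz, "DZ +", x$settings$n_mz, "MZ pairs\n")
  cat("Rejection proportions (test term per method):\n")
  print(x$rejection, digits = 4, row.names = FALSE)
  if (!is.null(x$h2)) {
    cat("Heritability estimates over replicates:\n")
    print(x$h2, digits = 4, row.names = FALSE)
  }
  invisible(x)
}

#' Power curve over a set of generating models
#'
#' Runs [run_replicates()] for one method across several generating
#' models (sharing a common test target) and tabulates the rejection
#' proportion per model — a type I error point when the generating effect
#' is zero, power otherwise.
#'
#' @param models named list of [twin_params()] objects.
#' @param method one method name.
#' @param n_reps replicates per model.
#' @param seed master seed (each model gets a derived seed).
#' @param ... passed to [run_replicates()].
#' @return Data frame: `model`, `effect` (the generating coefficient under
#'   test), `rejection`, `mc_se`, `n_used`.
#' @export
power_curve <- function(models, method, n_reps, seed = 1, ...) {
  stopifnot(is.list(models), length(models) >= 1L, length(method) == 1L)
  if (is.null(names(models))) names(models) <- paste0("model", seq_along(models))
  seeds <- derive_seeds(seed, length(models), salt = 5L)
  do.call(rbind, lapply(seq_along(models), function(i) {
    p <- models[[i]]
    rep <- run_replicates(p, method, n_reps, seed = seeds[i], ...)
    eff <- if (rep$settings$include_gxt) p$betaGT else p$betaG
    data.frame(model = names(models)[i], effect = eff,
               rejection = rep$rejection$rejection,
               mc_se = rep$rejection$mc_se,
               n_used = rep$rejection$n_used,
               stringsAsFactors = FALSE)
  }))
}

#' Mean (SD) estimate grid from a replicate evaluation
#'
#' Formats the replicate means and SDs of every estimated coefficient as
#' a methods-by-parameters character grid, the usual simulation-study
#' reporting surface.
#'
#' @param report a `twin_eval` object from [run_replicates()].
#' @param digits significant digits.
#' @param path optional CSV output path.
#' @return A data frame (rows = methods, columns = terms) of
#'   `"mean (sd)"` strings, invisibly written to `path` when given.
#' @export
estimate_table <- function(report, digits = 3, path = NULL) {
  stopifnot(inherits(report, "twin_eval"))
  est <- report$estimates
  terms <- unique(est$term)
  methods <- unique(est$method)
  grid <- matrix("", length(methods), length(terms),
                 dimnames = list(methods, terms))
  for (i in seq_len(nrow(est))) {
    grid[est$method[i], est$term[i]] <-
      sprintf("%s (%s)", signif(est$mean[i], digits),
              signif(est$sd[i], digits))
  }
  out <- data.frame(method = methods, grid, check.names = FALSE,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
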