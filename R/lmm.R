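# Likelihood-based analyses that simplify the familial correlation:
# a family random-intercept model for summary phenotypes, and a
# three-level hierarchical model for the full longitudinal table.
# Both are ML fits (not REML) so log-likelihoods are comparable across
# methods; Wald z tests against the standard normal.

lmer_quiet <- function(expr) {
  msgs <- character(0)
  fit <- withCallingHandlers(
    expr,
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m))
      invokeRestart("muffleMessage")
    }
  )
  list(fit = fit, messages = msgs)
}

hier_coefs <- function(fit) {
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- est / se
  data.frame(term = names(est), estimate = unname(est), se = unname(se),
             z = unname(z), p = 2 * stats::pnorm(-abs(z)),
             stringsAsFactors = FALSE)
}

#' Family random-intercept model for a summary phenotype
#'
#' Linear mixed model with a single random intercept per twin pair
#' (zygosity deliberately ignored: MZ and DZ pairs get the same
#' within-pair correlation) and fixed effects for sex and genotype.
#' This is the simplest "simplified familial correlation" analysis.
#'
#' @param data a per-twin data frame ([summarize_trajectories()] output).
#' @param response summary phenotype column.
#' @param covariates fixed-effect covariates.
#' @return An object of class `hier_fit`: `coefficients` (Wald z tests),
#'   `varcomp` (named vector: `pair` intercept variance, `residual`),
#'   `logLik`, `converged`, `messages`, and the fitted `model`.
#' @export
fit_family_lmm <- function(data, response = "mean",
                           covariates = c("sex", "genotype")) {
  stopifnot(inherits(data, "data.frame"), "pair_id" %in% names(data),
            response %in% names(data))
  fml <- stats::reformulate(c(covariates, "(1 | pair_id)"),
                            response = response)
  res <- lmer_quiet(lme4::lmer(fml, data = data, REML = FALSE))
  fit <- res$fit
  vc <- as.data.frame(lme4::VarCorr(fit))
  varcomp <- c(pair = vc$vcov[vc$grp == "pair_id"],
               residual = vc$vcov[vc$grp == "Residual"])
  out <- list(
    coefficients = hier_coefs(fit),
    varcomp = varcomp,
    logLik = as.numeric(stats::logLik(fit)),
    converged = length(fit@optinfo$conv$lme4) == 0L,
    messages = res$messages,
    formula = deparse(fml),
    model = fit
  )
  class(out) <- "hier_fit"
  out
}

#' Three-level hierarchical model for the longitudinal table
#'
#' The subject-specific longitudinal analysis with simplified familial
#' correlation: a random intercept at the pair level, a correlated random
#' intercept and random age slope at the individual level (unstructured
#' 2x2 covariance), an independent residual, and fixed effects for sex,
#' genotype, age in months and (optionally) genotype-by-age. Fit by
#' maximum likelihood with \pkg{lme4}.
#'
#' @param data a `twin_long` table.
#' @param include_gxt include the genotype-by-age fixed effect?
#' @return An object of class `hier_fit` (see [fit_family_lmm()]);
#'   `varcomp` holds `pair` (pair intercept variance), `ind_intercept`,
#'   `ind_slope`, `ind_cov` (individual-level 2x2 components) and
#'   `residual`; `singular` flags a boundary random-effects covariance.
#' @export
#' @examples
#' dat <- simulate_twin_data(sim_model("3a"), n_dz = 30, n_mz = 20, seed = 3)
#' fit <- fit_three_level(dat, include_gxt = TRUE)
#' fit$coefficients
fit_three_level <- function(data, include_gxt = FALSE) {
  stopifnot(inherits(data, "data.frame"),
            all(c("pair_id", "twin", "bmi", "age_months") %in% names(data)))
  data$indiv <- indiv_id(data$pair_id, data$twin)
  terms <- c("sex", "genotype", "age_months",
             if (include_gxt) "genotype:age_months",
             "(1 | pair_id)", "(1 + age_months | indiv)")
  fml <- stats::reformulate(terms, response = "bmi")
  res <- lmer_quiet(lme4::lmer(
    fml, data = data, REML = FALSE,
    control = lme4::lmerControl(check.conv.grad = "ignore",
                                check.conv.hess = "ignore",
                                check.conv.singular = "ignore",
                                calc.derivs = FALSE)))
  fit <- res$fit
  vc <- as.data.frame(lme4::VarCorr(fit))
  pick <- function(grp, v1, v2 = NA) {
    i <- vc$grp == grp & vc$var1 %in% v1 &
      (if (is.na(v2)) is.na(vc$var2) else vc$var2 %in% v2)
    if (any(i)) vc$vcov[i][1L] else NA_real_
  }
  varcomp <- c(
    pair = pick("pair_id", "(Intercept)"),
    ind_intercept = pick("indiv", "(Intercept)"),
    ind_slope = pick("indiv", "age_months"),
    ind_cov = pick("indiv", "(Intercept)", "age_months"),
    residual = vc$vcov[vc$grp == "Residual"]
  )
  out <- list(
    coefficients = hier_coefs(fit),
    varcomp = varcomp,
    logLik = as.numeric(stats::logLik(fit)),
    converged = length(fit@optinfo$conv$lme4) == 0L,
    singular = lme4::isSingular(fit),
    messages = res$messages,
    include_gxt = include_gxt,
    formula = deparse(fml),
    model = fit
  )
  class(out) <- "hier_fit"
  out
}

#' @export
print.hier_fit <- function(x, ...) {
  cat("Hierarchical linear mixed model (ML):", x$formula, "\n")
  print(x$coefficients, digits = 4, row.names = FALSE)
  cat("variance components:\n")
  print(round(x$varcomp, 6))
  cat("logLik =", round(x$logLik, 2), "| converged:", x$converged, "\n")
  invisible(x)
}
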