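# Classical twin ACE model: bivariate-normal maximum likelihood with the
# path-coefficient parameterization (a, c, e), which enforces non-negative
# variance components sigmaA2 = a^2, sigmaC2 = c^2, sigmaE2 = e^2.

# Pack pair-level structures once so the likelihood is cheap to evaluate.
ace_prepare <- function(data, response, covariates) {
  stopifnot(inherits(data, "data.frame"), response %in% names(data))
  miss <- setdiff(covariates, names(data))
  if (length(miss)) stop("missing covariates: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  data <- data[order(data$pair_id, data$twin), ]
  cnt <- table(data$pair_id)
  if (any(cnt != 2L)) {
    stop("ACE model needs complete pairs (2 twins per pair); offending pairs: ",
         paste(utils::head(names(cnt)[cnt != 2L], 5L), collapse = ", "),
         call. = FALSE)
  }
  X <- cbind(`(Intercept)` = 1,
             as.matrix(data[, covariates, drop = FALSE]))
  y <- data[[response]]
  i1 <- seq(1L, nrow(data), by = 2L)
  zyg <- data$zygosity[i1]
  if (!all(zyg %in% c("MZ", "DZ"))) stop("zygosity must be MZ or DZ",
                                         call. = FALSE)
  list(X = X, y = y, i1 = i1, i2 = i1 + 1L, is_mz = zyg == "MZ",
       n_pairs = length(i1), p = ncol(X))
}

# log-likelihood at beta (fixed effects) and path coefficients a, c, e
ace_loglik_prep <- function(prep, beta, a, c, e) {
  v <- a^2 + c^2 + e^2
  cv <- ifelse(prep$is_mz, a^2 + c^2, 0.5 * a^2 + c^2)
  det <- v^2 - cv^2
  if (any(det <= 0) || v <= 0) return(-Inf)
  r <- prep$y - drop(prep$X %*% beta)
  r1 <- r[prep$i1]; r2 <- r[prep$i2]
  quad <- (v * (r1^2 + r2^2) - 2 * cv * r1 * r2) / det
  sum(-log(2 * pi) - 0.5 * log(det) - 0.5 * quad)
}

#' ACE model log-likelihood
#'
#' Evaluates the twin ACE log-likelihood: for each complete pair the
#' bivariate normal log-density with per-twin mean \eqn{x'\beta}, common
#' variance \eqn{a^2+c^2+e^2}, and within-pair covariance \eqn{a^2+c^2}
#' (MZ) or \eqn{a^2/2+c^2} (DZ).
#'
#' @param data a per-twin data frame with `pair_id`, `twin`, `zygosity`,
#'   the response column and the covariates.
#' @param beta fixed-effect vector (intercept first, then `covariates` in
#'   order).
#' @param a,c,e path coefficients; variance components are their squares.
#' @param response name of the response column.
#' @param covariates covariate column names.
#' @return The log-likelihood (scalar; `-Inf` outside the parameter space).
#' @export
ace_loglik <- function(data, beta, a, c, e, response = "mean",
                       covariates = base::c("sex", "genotype")) {
  if (a == 0 && c == 0 && e == 0) {
    stop("singular implied covariance: a = c = e = 0", call. = FALSE)
  }
  prep <- ace_prepare(data, response, covariates)
  if (length(beta) != prep$p) {
    stop("`beta` must have length ", prep$p, " (intercept + covariates)",
         call. = FALSE)
  }
  ace_loglik_prep(prep, beta, a, c, e)
}

#' Fit the classical twin ACE model
#'
#' Maximum-likelihood fit of the ACE model to a per-twin summary
#' phenotype, with fixed effects for an intercept and the requested
#' covariates. Estimation uses the path-coefficient parameterization
#' (variance components are squares, hence non-negative) with multi-start
#' optimization from moment-based initial values; standard errors come
#' from the observed information at the optimum, and the genotype effect
#' is tested with a Wald statistic against the standard normal.
#'
#' @param data a per-twin data frame (typically [summarize_trajectories()]
#'   output) with `pair_id`, `twin`, `zygosity`, the response and
#'   covariates.
#' @param response summary phenotype column to analyse.
#' @param covariates fixed-effect covariates (besides the intercept).
#' @param n_starts number of optimization starts (>= 3 recommended; the
#'   first is moment-based, the rest jittered).
#' @return An object of class `ace_fit`: list with `coefficients` (term,
#'   estimate, se, z, p), `varcomp` (`sigmaA2`, `sigmaC2`, `sigmaE2`),
#'   `h2`, `logLik`, `converged`, `n_pairs`.
#' @export
#' @examples
#' dat <- simulate_twin_data(sim_model("1"), n_dz = 60, n_mz = 40, seed = 2)
#' fit <- fit_ace(summarize_trajectories(dat, "mean"), response = "mean")
#' heritability(fit)
fit_ace <- function(data, response = "mean",
                    covariates = c("sex", "genotype"), n_starts = 3L) {
  prep <- ace_prepare(data, response, covariates)
  p <- prep$p

  nll <- function(par) {
    ll <- ace_loglik_prep(prep, par[seq_len(p)], par[p + 1L], par[p + 2L],
                          par[p + 3L])
    if (!is.finite(ll)) 1e10 else -ll
  }

  # moment starts: OLS fixed effects, zygosity covariances for a, c, e
  beta0 <- stats::lm.fit(prep$X, prep$y)$coefficients
  r <- prep$y - drop(prep$X %*% beta0)
  r1 <- r[prep$i1]; r2 <- r[prep$i2]
  vtot <- stats::var(r)
  cmz <- if (any(prep$is_mz)) stats::cov(r1[prep$is_mz], r2[prep$is_mz]) else 0
  cdz <- if (any(!prep$is_mz)) stats::cov(r1[!prep$is_mz], r2[!prep$is_mz]) else 0
  a2 <- min(max(2 * (cmz - cdz), 0.05 * vtot), 0.9 * vtot)
  c2 <- min(max(2 * cdz - cmz, 0.05 * vtot), 0.9 * vtot)
  e2 <- max(vtot - a2 - c2, 0.05 * vtot)
  starts <- list(c(beta0, sqrt(a2), sqrt(c2), sqrt(e2)),
                 c(beta0, rep(sqrt(vtot / 3), 3L)),
                 c(beta0, sqrt(0.1 * vtot), sqrt(0.1 * vtot), sqrt(0.8 * vtot)))
  n_starts <- max(3L, as.integer(n_starts))
  while (length(starts) < n_starts) {
    starts[[length(starts) + 1L]] <-
      starts[[1L]] * stats::runif(p + 3L, 0.7, 1.3)
  }

  best <- NULL
  for (st in starts) {
    o1 <- stats::optim(st, nll, method = "Nelder-Mead",
                       control = list(maxit = 1000L))
    o2 <- tryCatch(
      stats::optim(o1$par, nll, method = "BFGS",
                   control = list(maxit = 200L)),
      error = function(e) o1)
    cand <- if (o2$value <= o1$value) o2 else o1
    if (is.null(best) || cand$value < best$value) best <- cand
  }

  par <- best$par
  H <- tryCatch(stats::optimHess(par, nll), error = function(e) NULL)
  se <- rep(NA_real_, p + 3L)
  if (!is.null(H)) {
    V <- tryCatch(solve(H), error = function(e) MASS::ginv(H))
    d <- diag(V)
    se <- ifelse(d > 0, sqrt(d), NA_real_)
  }

  est_beta <- par[seq_len(p)]
  se_beta <- se[seq_len(p)]
  z <- est_beta / se_beta
  coefs <- data.frame(
    term = colnames(prep$X),
    estimate = est_beta,
    se = se_beta,
    z = z,
    p = 2 * stats::pnorm(-abs(z)),
    stringsAsFactors = FALSE
  )
  vc <- c(sigmaA2 = par[p + 1L]^2, sigmaC2 = par[p + 2L]^2,
          sigmaE2 = par[p + 3L]^2)

  out <- list(
    coefficients = coefs,
    varcomp = vc,
    h2 = unname(vc[1L] / sum(vc)),
    logLik = -best$value,
    converged = best$convergence == 0L,
    optim_code = best$convergence,
    n_pairs = prep$n_pairs,
    response = response
  )
  class(out) <- "ace_fit"
  out
}

#' @rdname heritability
#' @export
heritability.ace_fit <- function(x, ...) heritability(unname(x$varcomp))

#' @export
print.ace_fit <- function(x, ...) {
  cat("Twin ACE model fit (ML), response:", x$response,
      "| pairs:", x$n_pairs, "\n")
  print(x$coefficients, digits = 4, row.names = FALSE)
  cat("variance components: sigmaA2 =", round(x$varcomp[1L], 4),
      ", sigmaC2 =", round(x$varcomp[2L], 4),
      ", sigmaE2 =", round(x$varcomp[3L], 4), "\n")
  cat("heritability h2 =", round(x$h2, 4),
      "| logLik =", round(x$logLik, 2),
      "| converged:", x$converged, "\n")
  invisible(x)
}
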