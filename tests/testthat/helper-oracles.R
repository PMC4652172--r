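# Independent oracles and small fixture builders used across test files.
# Everything here is deliberately naive (loops, generic matrix formulas,
# exhaustive enumeration) and shares no code with the package internals.

# generic multivariate normal log-density via matrix algebra
mvn_logdens <- function(y, mu, Sigma) {
  d <- length(y)
  r <- y - mu
  -0.5 * d * log(2 * pi) - 0.5 * determinant(Sigma)$modulus[1] -
    0.5 * drop(t(r) %*% solve(Sigma) %*% r)
}

# exact joint distribution of two DZ siblings' additive genotypes under
# Hardy-Weinberg parents and Mendelian transmission, by exhaustive
# enumeration of parental genotypes and transmitted alleles
dz_genotype_joint <- function(p) {
  hw <- c(`0` = (1 - p)^2, `1` = 2 * p * (1 - p), `2` = p^2)
  # P(transmitted allele is minor | parent genotype g) = g/2
  joint <- matrix(0, 3, 3, dimnames = list(0:2, 0:2))
  for (gm in 0:2) for (gf in 0:2) {
    pm <- gm / 2; pf <- gf / 2
    # child genotype pmf given parents: sum of two independent Bernoullis
    pmf <- function(pa, pb) c((1 - pa) * (1 - pb),
                              pa * (1 - pb) + (1 - pa) * pb,
                              pa * pb)
    child <- pmf(pm, pf)
    joint <- joint + hw[gm + 1] * hw[gf + 1] * outer(child, child)
  }
  joint
}

dz_genotype_corr <- function(p) {
  J <- dz_genotype_joint(p)
  g <- 0:2
  m <- sum(outer(g, g, function(a, b) a) * J)
  v <- sum(outer(g, g, function(a, b) a^2) * J) - m^2
  cv <- sum(outer(g, g) * J) - m^2
  cv / v
}

# hand-rolled per-twin trapezoid quadrature
trapz_oracle <- function(t, y) {
  s <- 0
  for (k in seq_len(length(t) - 1)) {
    s <- s + 0.5 * (y[k] + y[k + 1]) * (t[k + 1] - t[k])
  }
  s
}

# hand-rolled per-twin OLS of y on t via the normal equations
ols_oracle <- function(t, y) {
  A <- cbind(1, t)
  unname(solve(t(A) %*% A, t(A) %*% y)[, 1])
}

# naive loop-based Gaussian GEE (identity link): explicit per-cluster
# matrices, fixed-point iteration of the closed-form updates
gee_oracle <- function(y, X, cluster, structure, maxit = 200, tol = 1e-10) {
  cl <- split(seq_along(y), cluster)
  m <- length(cl[[1]])
  K <- length(cl)
  p <- ncol(X)
  beta <- solve(t(X) %*% X, t(X) %*% y)[, 1]
  R <- diag(m)
  for (it in seq_len(maxit)) {
    e <- y - X %*% beta
    phi <- sum(e^2) / (length(y) - p)
    if (structure == "exchangeable") {
      num <- 0
      for (idx in cl) {
        ei <- e[idx]
        for (j in 1:(m - 1)) for (k in (j + 1):m) num <- num + ei[j] * ei[k]
      }
      rho <- num / ((K * m * (m - 1) / 2 - p) * phi)
      R <- matrix(rho, m, m); diag(R) <- 1
    } else if (structure == "ar1") {
      num <- 0
      for (idx in cl) {
        ei <- e[idx]
        for (j in 1:(m - 1)) num <- num + ei[j] * ei[j + 1]
      }
      rho <- num / ((K * (m - 1) - p) * phi)
      R <- rho^abs(outer(1:m, 1:m, "-"))
    } else if (structure == "unstructured") {
      R <- matrix(0, m, m)
      for (idx in cl) R <- R + e[idx] %*% t(e[idx])
      R <- R / ((K - p) * phi)
      diag(R) <- 1
    }
    A <- matrix(0, p, p); b <- rep(0, p)
    W <- solve(R)
    for (idx in cl) {
      Xi <- X[idx, , drop = FALSE]
      A <- A + t(Xi) %*% W %*% Xi
      b <- b + t(Xi) %*% W %*% y[idx]
    }
    beta_new <- solve(A, b)[, 1]
    if (sqrt(sum((beta_new - beta)^2)) < tol * max(1, sqrt(sum(beta^2)))) {
      beta <- beta_new; break
    }
    beta <- beta_new
  }
  e <- y - X %*% beta
  phi <- sum(e^2) / (length(y) - p)
  W <- solve(R)
  B <- matrix(0, p, p); M <- matrix(0, p, p)
  for (idx in cl) {
    Xi <- X[idx, , drop = FALSE]
    B <- B + t(Xi) %*% W %*% Xi / phi
    u <- t(Xi) %*% W %*% e[idx] / phi
    M <- M + u %*% t(u)
  }
  V <- solve(B) %*% M %*% solve(B)
  list(beta = beta, R = R, rho = if (exists("rho")) rho else NA, vcov = V)
}

# per-family 12x12 marginal covariance implied by the three-level model
# (pair intercept + individual intercept/slope with 2x2 covariance +
# residual); ages in the order twin 1 visits then twin 2 visits
family_cov_oracle <- function(vc, ages) {
  m <- length(ages)
  G <- matrix(c(vc[["ind_intercept"]], vc[["ind_cov"]],
                vc[["ind_cov"]], vc[["ind_slope"]]), 2, 2)
  Zi <- cbind(1, ages)
  blk <- Zi %*% G %*% t(Zi)
  S <- matrix(vc[["pair"]], 2 * m, 2 * m)
  S[1:m, 1:m] <- S[1:m, 1:m] + blk
  S[(m + 1):(2 * m), (m + 1):(2 * m)] <- S[(m + 1):(2 * m), (m + 1):(2 * m)] + blk
  S + diag(vc[["residual"]], 2 * m)
}

# small deterministic long table: one value per (pair, twin, visit)
make_long_table <- function(bmi_fun, n_pairs = 2,
                            ages = c(1, 6, 18, 30, 48, 60),
                            zygosity = rep(c("MZ", "DZ"), length.out = n_pairs),
                            sex = 0L, genotype = 0L) {
  rows <- expand.grid(visit = seq_along(ages), twin = 1:2,
                      pair_id = seq_len(n_pairs))
  rows <- rows[order(rows$pair_id, rows$twin, rows$visit), ]
  rows$zygosity <- zygosity[rows$pair_id]
  rows$sex <- sex
  rows$genotype <- genotype
  rows$age_months <- ages[rows$visit]
  rows$age_post_knot <- ifelse(rows$visit <= 2, 0, rows$age_months - 6)
  rows$bmi <- mapply(bmi_fun, rows$pair_id, rows$twin, rows$age_months)
  rownames(rows) <- NULL
  rows[, c("pair_id", "twin", "zygosity", "sex", "genotype", "visit",
           "age_months", "age_post_knot", "bmi")]
}
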