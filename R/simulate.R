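#' Build a twin cohort design
#'
#' Creates the pedigree-and-visit frame for a cohort of DZ and MZ twin
#' pairs: pair ids, zygosity, per-twin sex, and six per-visit ages in
#' months. Sex is assigned with equal probability, per pair for MZ twins
#' (who are always sex-concordant) and per twin for DZ pairs.
#'
#' `visit_ages` is either a fixed schedule (a strictly increasing numeric
#' vector of six ages, applied to every twin) or a list of six per-visit
#' age pools. With pools, each twin's visit-k age is an independent draw
#' from pool k; the six draws are then sorted, emulating cohorts where
#' observed visit ages vary between children. In both cases the first two
#' visits must not exceed the knot, because the segmented age is defined as
#' \eqn{T'_{ijk} = 0} for \eqn{k \le 2} and \eqn{T_{ijk} - \mathrm{knot}}
#' for \eqn{k > 2}.
#'
#' @param n_dz,n_mz numbers of dizygotic and monozygotic pairs (>= 0, at
#'   least one pair in total).
#' @param visit_ages fixed schedule (numeric, length 6, months) or list of
#'   6 numeric age pools. Default `c(1, 6, 18, 30, 48, 60)` months: two
#'   visits at or before the 6-month knot, then follow-up to five years.
#' @param knot knot age in months for the segmented time effect.
#' @param seed optional integer seed (only consumed when pools are used or
#'   for the sex assignment).
#' @return A data frame of class `twin_design`, one row per twin-visit,
#'   with columns `pair_id`, `twin`, `zygosity`, `sex`, `visit`,
#'   `age_months`, and attribute `knot`.
#' @export
#' @examples
#' d <- build_design(2, 1, seed = 1)
#' table(d$zygosity) / 6  # twins per zygosity
build_design <- function(n_dz, n_mz,
                         visit_ages = c(1, 6, 18, 30, 48, 60),
                         knot = 6, seed = NULL) {
  n_dz <- as.integer(n_dz); n_mz <- as.integer(n_mz)
  if (is.na(n_dz) || is.na(n_mz) || n_dz < 0 || n_mz < 0 || n_dz + n_mz < 1) {
    stop("need non-negative pair counts with at least one pair", call. = FALSE)
  }
  pooled <- is.list(visit_ages)
  n_vis <- length(visit_ages)
  if (n_vis != 6L) {
    stop("`visit_ages` must describe exactly 6 visits, got ", n_vis,
         call. = FALSE)
  }
  if (pooled) {
    if (!all(vapply(visit_ages, function(p) is.numeric(p) && length(p) >= 1L,
                    TRUE))) {
      stop("each age pool must be a non-empty numeric vector", call. = FALSE)
    }
    if (max(visit_ages[[1L]]) > knot || max(visit_ages[[2L]]) > knot) {
      stop("age pools for visits 1-2 must not exceed the knot (",
           knot, " months): the segmented age is 0 for those visits",
           call. = FALSE)
    }
  } else {
    if (!is.numeric(visit_ages) || any(diff(visit_ages) <= 0)) {
      stop("a fixed schedule must be strictly increasing ages in months",
           call. = FALSE)
    }
    if (visit_ages[2L] > knot) {
      stop("visit-2 age (", visit_ages[2L], ") exceeds the knot (", knot,
           " months); the first two visits must be at or before the knot",
           call. = FALSE)
    }
  }

  maybe_set_seed(seed)
  n_pairs <- n_dz + n_mz
  zyg_pair <- rep(c("DZ", "MZ"), c(n_dz, n_mz))
  # sex: per twin for DZ, per pair (concordant) for MZ
  sex1 <- stats::rbinom(n_pairs, 1L, 0.5)
  sex2 <- ifelse(zyg_pair == "MZ", sex1, stats::rbinom(n_pairs, 1L, 0.5))

  n_twins <- 2L * n_pairs
  if (pooled) {
    ages <- matrix(0, nrow = n_twins, ncol = 6L)
    for (k in 1:6) {
      pool <- visit_ages[[k]]
      ages[, k] <- pool[sample.int(length(pool), n_twins, replace = TRUE)]
    }
    ages <- t(apply(ages, 1L, sort))
    bad <- apply(ages, 1L, function(a) any(diff(a) <= 0))
    tries <- 0L
    while (any(bad) && tries < 50L) {  # redraw ties; pools may overlap
      for (k in 1:6) {
        pool <- visit_ages[[k]]
        ages[bad, k] <- pool[sample.int(length(pool), sum(bad), replace = TRUE)]
      }
      ages[bad, ] <- t(apply(ages[bad, , drop = FALSE], 1L, sort))
      bad <- apply(ages, 1L, function(a) any(diff(a) <= 0))
      tries <- tries + 1L
    }
    if (any(bad)) {
      stop("could not draw strictly increasing ages from the supplied pools",
           call. = FALSE)
    }
  } else {
    ages <- matrix(visit_ages, nrow = n_twins, ncol = 6L, byrow = TRUE)
  }

  out <- data.frame(
    pair_id = rep(seq_len(n_pairs), each = 12L),
    twin = rep(rep(1:2, each = 6L), n_pairs),
    zygosity = rep(zyg_pair, each = 12L),
    sex = rep(as.integer(rbind(sex1, sex2)), each = 6L),
    visit = rep(1:6, n_twins),
    age_months = as.numeric(t(ages)),
    stringsAsFactors = FALSE
  )
  attr(out, "knot") <- knot
  class(out) <- c("twin_design", "data.frame")
  out
}

#' Simulate SNP genotypes by Mendelian transmission
#'
#' Assigns each pair two parents with Hardy--Weinberg genotypes at the
#' given minor allele frequency, then transmits one allele per parent to
#' each DZ twin independently; for MZ pairs one genotype is transmitted and
#' duplicated in the co-twin. Genotypes are additive counts of the minor
#' allele (0/1/2).
#'
#' @param design a [build_design()] frame.
#' @param maf minor allele frequency in `[0, 1)`; 0 is permitted as a
#'   degenerate edge (all genotypes 0).
#' @param seed optional integer seed.
#' @return A data frame of class `twin_genotypes` with one row per twin:
#'   `pair_id`, `twin`, `genotype`.
#' @export
simulate_genotypes <- function(design, maf = 0.3, seed = NULL) {
  stopifnot(inherits(design, "twin_design"))
  if (length(maf) != 1L || !is.finite(maf) || maf < 0 || maf >= 1) {
    stop("`maf` must be a single frequency in [0, 1)", call. = FALSE)
  }
  maybe_set_seed(seed)
  twins <- unique(design[, c("pair_id", "twin", "zygosity")])
  twins <- twins[order(twins$pair_id, twins$twin), ]
  pairs <- unique(twins[, c("pair_id", "zygosity")])
  n_pairs <- nrow(pairs)

  # parental alleles: 1 = minor allele carried
  mum <- matrix(stats::rbinom(2L * n_pairs, 1L, maf), ncol = 2L)
  dad <- matrix(stats::rbinom(2L * n_pairs, 1L, maf), ncol = 2L)
  transmit <- function() {  # one child per pair: one allele per parent
    mi <- sample(1:2, n_pairs, replace = TRUE)
    di <- sample(1:2, n_pairs, replace = TRUE)
    mum[cbind(seq_len(n_pairs), mi)] + dad[cbind(seq_len(n_pairs), di)]
  }
  g1 <- transmit()
  g2 <- transmit()
  g2[pairs$zygosity == "MZ"] <- g1[pairs$zygosity == "MZ"]  # duplicate MZ

  out <- data.frame(
    pair_id = rep(pairs$pair_id, each = 2L),
    twin = rep(1:2, n_pairs),
    genotype = as.integer(rbind(g1, g2)),
    stringsAsFactors = FALSE
  )
  attr(out, "maf") <- maf
  class(out) <- c("twin_genotypes", "data.frame")
  out
}

# Pair-level covariance matrices for intercept/slope random effects:
# variance sA2 + sC2, within-pair covariance sA2 + sC2 (MZ) or sA2/2 + sC2
# (DZ); used both for simulation and for closed-form checks.
pair_cov <- function(sA2, sC2, zygosity) {
  cv <- if (zygosity == "MZ") sA2 + sC2 else 0.5 * sA2 + sC2
  matrix(c(sA2 + sC2, cv, cv, sA2 + sC2), 2L, 2L)
}

# draw n pairs from a 2x2 zero-mean normal with the pair_cov structure
rpair_bvn <- function(n, sA2, sC2, zygosity) {
  S <- pair_cov(sA2, sC2, zygosity)
  if (all(S == 0)) return(matrix(0, n, 2L))
  L <- t(chol(S + diag(1e-12, 2L)))
  t(L %*% matrix(stats::rnorm(2L * n), 2L, n))
}

#' Draw twin-structured random intercepts and slopes
#'
#' Draws the per-twin random intercepts \eqn{\beta_{0ij}} and random age
#' slopes \eqn{\beta_{Tij}} under the twin variance-components structure:
#' variance \eqn{\sigma_A^2+\sigma_C^2} with within-pair covariance
#' \eqn{\sigma_A^2+\sigma_C^2} (MZ) or \eqn{\sigma_A^2/2+\sigma_C^2} (DZ),
#' and the \eqn{\tau} analogues for slopes. Intercept and slope effects are
#' independent of each other.
#'
#' Two equivalent constructions are available: the pair/individual
#' decomposition (MZ: a single pair effect
#' \eqn{\mathrm{Pair} \sim N(0, \sigma_A^2+\sigma_C^2)}; DZ: a pair effect
#' \eqn{N(0, \sigma_A^2/2+\sigma_C^2)} plus per-twin individual effects
#' \eqn{N(0, \sigma_A^2/2)}), or a direct bivariate-normal draw per pair.
#' Both target the same distribution; the decomposition is also the latent
#' parameterization used by the Bayesian sampler.
#'
#' @param design a [build_design()] frame.
#' @param params a [twin_params()] object.
#' @param seed optional integer seed.
#' @param method `"pair_individual"` (default) or `"bivariate"`.
#' @return A data frame of class `twin_raneff`, one row per twin, with
#'   columns `pair_id`, `twin`, `b0` (random intercept), `bT` (random
#'   slope) and, under the decomposition, the latent `pair0`, `ind0`,
#'   `pairT`, `indT` components.
#' @export
draw_random_effects <- function(design, params, seed = NULL,
                                method = c("pair_individual", "bivariate")) {
  stopifnot(inherits(design, "twin_design"), inherits(params, "twin_params"))
  vcs <- unlist(params[c("sigmaA2", "sigmaC2", "tauA2", "tauC2")])
  if (any(!is.finite(vcs)) || any(vcs < 0)) {
    stop("negative or non-finite variance component(s): ",
         paste(names(vcs)[!is.finite(vcs) | vcs < 0], collapse = ", "),
         call. = FALSE)
  }
  method <- match.arg(method)
  maybe_set_seed(seed)
  pairs <- unique(design[, c("pair_id", "zygosity")])
  pairs <- pairs[order(pairs$pair_id), ]
  n <- nrow(pairs)
  is_mz <- pairs$zygosity == "MZ"

  if (method == "pair_individual") {
    draw_level <- function(vA2, vC2) {
      pair_sd <- ifelse(is_mz, sqrt(vA2 + vC2), sqrt(0.5 * vA2 + vC2))
      pair_eff <- stats::rnorm(n, 0, pair_sd)
      ind_sd <- ifelse(is_mz, 0, sqrt(0.5 * vA2))
      ind <- cbind(stats::rnorm(n, 0, ind_sd), stats::rnorm(n, 0, ind_sd))
      list(pair = pair_eff, ind = ind, total = pair_eff + ind)
    }
    lev0 <- draw_level(params$sigmaA2, params$sigmaC2)
    levT <- draw_level(params$tauA2, params$tauC2)
    out <- data.frame(
      pair_id = rep(pairs$pair_id, each = 2L),
      twin = rep(1:2, n),
      b0 = as.numeric(t(lev0$total)),
      bT = as.numeric(t(levT$total)),
      pair0 = rep(lev0$pair, each = 2L),
      ind0 = as.numeric(t(lev0$ind)),
      pairT = rep(levT$pair, each = 2L),
      indT = as.numeric(t(levT$ind)),
      stringsAsFactors = FALSE
    )
  } else {
    b0 <- matrix(0, n, 2L); bT <- matrix(0, n, 2L)
    for (z in c("MZ", "DZ")) {
      idx <- pairs$zygosity == z
      if (!any(idx)) next
      b0[idx, ] <- rpair_bvn(sum(idx), params$sigmaA2, params$sigmaC2, z)
      bT[idx, ] <- rpair_bvn(sum(idx), params$tauA2, params$tauC2, z)
    }
    out <- data.frame(
      pair_id = rep(pairs$pair_id, each = 2L),
      twin = rep(1:2, n),
      b0 = as.numeric(t(b0)),
      bT = as.numeric(t(bT)),
      stringsAsFactors = FALSE
    )
  }
  class(out) <- c("twin_raneff", "data.frame")
  out
}

#' Simulate longitudinal phenotypes
#'
#' Generates the long-format phenotype table from a design, genotypes and
#' parameters under the segmented linear growth model
#' \eqn{Y_{ijk} = (\beta_0+\beta_{0ij}) + \beta_S S_{ij} + \beta_G G_{ij}
#' + (\beta_T+\beta_{Tij}) T_{ijk} + \beta_{T'} T'_{ijk}
#' + \beta_{GT} G_{ij} T_{ijk} + \epsilon_{ijk}} with independent
#' \eqn{N(0, \sigma_E^2)} residuals. The segmented age is
#' \eqn{T'_{ijk} = 0} for visits 1--2 and \eqn{T_{ijk} - \mathrm{knot}}
#' afterwards.
#'
#' @param design a [build_design()] frame.
#' @param genotypes a [simulate_genotypes()] frame for the same design.
#' @param params a [twin_params()] object.
#' @param seed optional integer seed (residuals and, if `raneff` is NULL,
#'   random effects).
#' @param raneff optional pre-drawn [draw_random_effects()] frame; drawn
#'   internally when NULL.
#' @return A data frame of class `twin_long`, one row per twin-visit, with
#'   columns `pair_id`, `twin`, `zygosity`, `sex`, `genotype`, `visit`,
#'   `age_months`, `age_post_knot`, `bmi`.
#' @export
simulate_phenotypes <- function(design, genotypes, params, seed = NULL,
                                raneff = NULL) {
  stopifnot(inherits(design, "twin_design"), inherits(params, "twin_params"))
  n_twins_d <- nrow(unique(design[, c("pair_id", "twin")]))
  if (!inherits(genotypes, "twin_genotypes") ||
      nrow(genotypes) != n_twins_d ||
      !all(genotypes$pair_id %in% design$pair_id)) {
    stop("`genotypes` does not match `design` (one genotype per twin required)",
         call. = FALSE)
  }
  maybe_set_seed(seed)
  if (is.null(raneff)) raneff <- draw_random_effects(design, params)
  knot <- attr(design, "knot")

  dat <- merge(design, genotypes, by = c("pair_id", "twin"), sort = FALSE)
  dat <- merge(dat, raneff[, c("pair_id", "twin", "b0", "bT")],
               by = c("pair_id", "twin"), sort = FALSE)
  dat <- dat[order(dat$pair_id, dat$twin, dat$visit), ]
  dat$age_post_knot <- ifelse(dat$visit <= 2L, 0, dat$age_months - knot)

  mu <- (params$beta0 + dat$b0) + params$betaS * dat$sex +
    params$betaG * dat$genotype +
    (params$betaT + dat$bT) * dat$age_months +
    params$betaTprime * dat$age_post_knot +
    params$betaGT * dat$genotype * dat$age_months
  dat$bmi <- mu + stats::rnorm(nrow(dat), 0, sqrt(params$sigmaE2))

  out <- dat[, c("pair_id", "twin", "zygosity", "sex", "genotype",
                 "visit", "age_months", "age_post_knot", "bmi")]
  rownames(out) <- NULL
  attr(out, "knot") <- knot
  class(out) <- c("twin_long", "data.frame")
  out
}

#' Simulate a complete twin cohort dataset
#'
#' One-call generator: builds the design, simulates genotypes, random
#' effects and phenotypes. The master seed is expanded into independent
#' substreams for the four stages, so each component can be regenerated
#' independently and the whole table is reproducible byte-for-byte.
#'
#' @inheritParams build_design
#' @param params a [twin_params()] object (its `maf` drives the genotypes).
#' @param seed integer master seed.
#' @return A `twin_long` data frame (see [simulate_phenotypes()]).
#' @export
#' @examples
#' dat <- simulate_twin_data(sim_model("1"), n_dz = 5, n_mz = 5, seed = 7)
#' head(dat)
simulate_twin_data <- function(params, n_dz = 226, n_mz = 168,
                               visit_ages = c(1, 6, 18, 30, 48, 60),
                               knot = 6, seed = 1) {
  stopifnot(inherits(params, "twin_params"))
  s <- derive_seeds(seed, 4L)
  design <- build_design(n_dz, n_mz, visit_ages, knot, seed = s[1L])
  geno <- simulate_genotypes(design, params$maf, seed = s[2L])
  re <- draw_random_effects(design, params, seed = s[3L])
  simulate_phenotypes(design, geno, params, seed = s[4L], raneff = re)
}

#' Read/write the long-format phenotype table
#'
#' Plain-CSV interchange with header `pair_id, twin, zygosity, sex,
#' genotype, visit, age_months, age_post_knot, bmi`.
#'
#' @param x a `twin_long` data frame.
#' @param path file path.
#' @param knot knot age used when reading (recorded as an attribute).
#' @return `read_twin_csv` returns a `twin_long` data frame;
#'   `write_twin_csv` returns `path` invisibly.
#' @export
write_twin_csv <- function(x, path) {
  stopifnot(inherits(x, "twin_long"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_twin_csv
#' @export
read_twin_csv <- function(path, knot = 6) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("pair_id", "twin", "zygosity", "sex", "genotype",
            "visit", "age_months", "age_post_knot", "bmi")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  x <- x[order(x$pair_id, x$twin, x$visit), need]
  rownames(x) <- NULL
  attr(x, "knot") <- knot
  class(x) <- c("twin_long", "data.frame")
  x
}

#' Export genotypes in PED-like text format
#'
#' Writes one row per twin with columns family id, individual id, father
#' id, mother id, sex (1 = male, 2 = female, following the convention that
#' the 0/1 simulation code maps to 1/2), and two allele columns (allele
#' `2` = minor). Parent genotypes are not simulated output and are written
#' as missing (`0 0`).
#'
#' @param design a [build_design()] frame.
#' @param genotypes the matching [simulate_genotypes()] frame.
#' @param path file path.
#' @export
write_ped <- function(design, genotypes, path) {
  stopifnot(inherits(design, "twin_design"), inherits(genotypes, "twin_genotypes"))
  tw <- unique(design[, c("pair_id", "twin", "sex")])
  tw <- merge(tw, genotypes, by = c("pair_id", "twin"), sort = FALSE)
  tw <- tw[order(tw$pair_id, tw$twin), ]
  a1 <- ifelse(tw$genotype >= 1L, 2L, 1L)
  a2 <- ifelse(tw$genotype == 2L, 2L, 1L)
  ped <- data.frame(
    fam = paste0("F", tw$pair_id),
    id = paste0("F", tw$pair_id, "_", tw$twin),
    father = paste0("F", tw$pair_id, "_F"),
    mother = paste0("F", tw$pair_id, "_M"),
    sex = tw$sex + 1L,
    a1 = a1, a2 = a2
  )
  parents <- data.frame(
    fam = rep(paste0("F", unique(tw$pair_id)), each = 2L),
    id = paste0("F", rep(unique(tw$pair_id), each = 2L), c("_F", "_M")),
    father = "0", mother = "0",
    sex = rep(1:2, length(unique(tw$pair_id))),
    a1 = 0L, a2 = 0L
  )
  utils::write.table(rbind(parents, ped), path, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}
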