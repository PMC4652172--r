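#' Simulation parameters for the twin growth model
#'
#' Bundles the fixed effects and variance components of the longitudinal twin
#' growth model. The phenotype for twin \eqn{j} of pair \eqn{i} at visit
#' \eqn{k} is generated as
#' \deqn{Y_{ijk} = (\beta_0 + \beta_{0ij}) + \beta_S S_{ij} + \beta_G G_{ij}
#'   + (\beta_T + \beta_{Tij}) T_{ijk} + \beta_{T'} T'_{ijk}
#'   + \beta_{GT} G_{ij} T_{ijk} + \epsilon_{ijk},}
#' with \eqn{\epsilon_{ijk} \sim N(0, \sigma_E^2)} independent across records,
#' twin-structured random intercepts \eqn{\beta_{0ij}} (variance
#' \eqn{\sigma_A^2 + \sigma_C^2}, within-pair covariance
#' \eqn{\sigma_A^2 + \sigma_C^2} for MZ and \eqn{\sigma_A^2/2 + \sigma_C^2}
#' for DZ pairs) and random age slopes \eqn{\beta_{Tij}} with the analogous
#' \eqn{\tau_A^2, \tau_C^2} structure. \eqn{T'} is the post-knot segmented
#' age (see [build_design()]).
#'
#' @param beta0 fixed intercept (phenotype units, e.g. BMI kg/m^2).
#' @param betaS fixed sex effect (sex coded 0/1).
#' @param betaG fixed additive genotype effect per minor allele.
#' @param betaT fixed age slope, per month.
#' @param betaTprime additional post-knot age slope, per month.
#' @param betaGT genotype-by-age interaction, per minor allele per month.
#' @param sigmaA2,sigmaC2,sigmaE2 additive-genetic, common-environment and
#'   residual variance components of the intercept/occasion level.
#' @param tauA2,tauC2 additive-genetic and common-environment variance
#'   components of the random age slope.
#' @param maf minor allele frequency of the simulated SNP.
#'
#' @return An object of class `twin_params` (a named list).
#' @seealso [sim_model()] for the built-in parameter presets,
#'   [simulate_twin_data()] for the generator.
#' @export
#' @examples
#' p <- twin_params(sigmaA2 = 4.5, sigmaC2 = 2.25, sigmaE2 = 2.25)
#' heritability(p)
twin_params <- function(beta0 = 11, betaS = 0.5, betaG = 0, betaT = 0.04,
                        betaTprime = 0, betaGT = 0,
                        sigmaA2 = 0, sigmaC2 = 0, sigmaE2 = 1,
                        tauA2 = 0, tauC2 = 0, maf = 0.3) {
  vcs <- c(sigmaA2 = sigmaA2, sigmaC2 = sigmaC2, sigmaE2 = sigmaE2,
           tauA2 = tauA2, tauC2 = tauC2)
  if (any(!is.finite(vcs)) || any(vcs < 0)) {
    stop("variance components must be finite and >= 0; got ",
         paste(names(vcs)[vcs < 0 | !is.finite(vcs)], collapse = ", "),
         call. = FALSE)
  }
  stop_if_not_scalar_prob(maf, "maf")
  fixed <- c(beta0 = beta0, betaS = betaS, betaG = betaG, betaT = betaT,
             betaTprime = betaTprime, betaGT = betaGT)
  if (any(!is.finite(fixed))) stop("fixed effects must be finite", call. = FALSE)
  structure(c(as.list(fixed), as.list(vcs), list(maf = maf)),
            class = "twin_params")
}

#' @export
print.twin_params <- function(x, ...) {
  cat("Twin growth simulation parameters\n")
  cat("  fixed effects: beta0 =", x$beta0, ", betaS =", x$betaS,
      ", betaG =", x$betaG, ", betaT =", x$betaT,
      ", betaT' =", x$betaTprime, ", betaGT =", x$betaGT, "\n")
  cat("  intercept variances: sigmaA2 =", x$sigmaA2,
      ", sigmaC2 =", x$sigmaC2, ", sigmaE2 =", x$sigmaE2, "\n")
  cat("  slope variances:     tauA2 =", x$tauA2, ", tauC2 =", x$tauC2, "\n")
  cat("  SNP minor allele frequency:", x$maf, "\n")
  cat("  implied heritability:", round(heritability(x), 4), "\n")
  invisible(x)
}

# The nine built-in simulation models. Columns: no genetic effect (1),
# effect on the average (2a-2d), linear effect on change (3a-3b) and
# segmented effect on change (4a-4b). Shared: beta0 = 11, betaS = 0.5,
# maf = 0.3.
.sim_models <- list(
  "1"  = list(betaG = 0,    betaT = 0.04, betaTprime = 0,    betaGT = 0,
              sigmaA2 = 4.5, sigmaC2 = 2.25, tauA2 = 0,     tauC2 = 0,
              sigmaE2 = 2.25),
  "2a" = list(betaG = 0.1,  betaT = 0.04, betaTprime = 0,    betaGT = 0,
              sigmaA2 = 4.3, sigmaC2 = 2.25, tauA2 = 0,     tauC2 = 0,
              sigmaE2 = 2.25),
  "2b" = list(betaG = 0.15, betaT = 0.04, betaTprime = 0,    betaGT = 0,
              sigmaA2 = 4.3, sigmaC2 = 2.25, tauA2 = 0,     tauC2 = 0,
              sigmaE2 = 2.25),
  "2c" = list(betaG = 0.2,  betaT = 0.04, betaTprime = 0,    betaGT = 0,
              sigmaA2 = 4.3, sigmaC2 = 2.25, tauA2 = 0,     tauC2 = 0,
              sigmaE2 = 2.25),
  "2d" = list(betaG = 0.3,  betaT = 0.04, betaTprime = 0,    betaGT = 0,
              sigmaA2 = 4.3, sigmaC2 = 2.25, tauA2 = 0,     tauC2 = 0,
              sigmaE2 = 2.25),
  "3a" = list(betaG = 0,    betaT = 0.04, betaTprime = 0,    betaGT = 0.005,
              sigmaA2 = 3,   sigmaC2 = 1.5,  tauA2 = 0.001, tauC2 = 0.001,
              sigmaE2 = 1.5),
  "3b" = list(betaG = 0,    betaT = 0.04, betaTprime = 0,    betaGT = 0.01,
              sigmaA2 = 3,   sigmaC2 = 1.5,  tauA2 = 0.001, tauC2 = 0.001,
              sigmaE2 = 1.5),
  "4a" = list(betaG = 0,    betaT = 0.8,  betaTprime = -0.8, betaGT = 0.005,
              sigmaA2 = 3,   sigmaC2 = 1.5,  tauA2 = 0.001, tauC2 = 0.001,
              sigmaE2 = 1.5),
  "4b" = list(betaG = 0,    betaT = 0.8,  betaTprime = -0.8, betaGT = 0.01,
              sigmaA2 = 3,   sigmaC2 = 1.5,  tauA2 = 0.001, tauC2 = 0.001,
              sigmaE2 = 1.5)
)

#' Built-in simulation model presets
#'
#' Returns the parameter set of one of the nine built-in simulation models:
#' `"1"` (no genetic effect, used for type I error), `"2a"`--`"2d"`
#' (genotype effect on the average phenotype, \eqn{\beta_G} = 0.1, 0.15,
#' 0.2, 0.3), `"3a"`--`"3b"` (linear genotype effect on the rate of change,
#' \eqn{\beta_{GT}} = 0.005, 0.01) and `"4a"`--`"4b"` (segmented genotype
#' effect on the rate of change). All models imply heritability
#' \eqn{\sigma_A^2 / (\sigma_A^2 + \sigma_C^2 + \sigma_E^2) = 0.5} at a
#' single occasion.
#'
#' @param name one of `"1"`, `"2a"`, `"2b"`, `"2c"`, `"2d"`, `"3a"`,
#'   `"3b"`, `"4a"`, `"4b"`.
#' @return A [twin_params()] object.
#' @export
#' @examples
#' sim_model("2d")$betaG   # 0.3
sim_model <- function(name) {
  name <- as.character(name)
  if (length(name) != 1L || !name %in% names(.sim_models)) {
    stop("unknown simulation model ", deparse(name), "; valid names: ",
         paste(names(.sim_models), collapse = ", "), call. = FALSE)
  }
  do.call(twin_params, .sim_models[[name]])
}

#' Heritability
#'
#' Narrow-sense heritability as the ratio of the additive-genetic variance to
#' the total phenotypic variance,
#' \eqn{h^2 = \sigma_A^2 / (\sigma_A^2 + \sigma_C^2 + \sigma_E^2)}.
#'
#' @param x a [twin_params()] object, an [fit_ace()] fit, or a numeric
#'   vector `c(sigmaA2, sigmaC2, sigmaE2)`.
#' @param ... unused.
#' @return Heritability in `[0, 1]`.
#' @export
heritability <- function(x, ...) UseMethod("heritability")

#' @rdname heritability
#' @export
heritability.twin_params <- function(x, ...) {
  heritability(c(x$sigmaA2, x$sigmaC2, x$sigmaE2))
}

#' @rdname heritability
#' @export
heritability.default <- function(x, ...) {
  stopifnot(is.numeric(x), length(x) == 3L, all(x >= 0))
  tot <- sum(x)
  if (tot <= 0) stop("heritability undefined: all variance components are zero",
                     call. = FALSE)
  x[[1L]] / tot
}
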