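#' Per-individual summary phenotypes
#'
#' Collapses each twin's six measurements into summary phenotypes: the
#' `mean` over visits, the `intercept` and `slope` of a per-individual
#' ordinary least-squares regression of the phenotype on age in months
#' (uncentered, so the intercept is the extrapolated phenotype at age 0),
#' and the trapezoidal area under the trajectory (`auc`).
#'
#' @param data a `twin_long` table (see [simulate_phenotypes()]).
#' @param stats which summaries to compute.
#' @return A data frame of class `twin_summaries`, one row per twin, with
#'   columns `pair_id`, `twin`, `zygosity`, `sex`, `genotype` and one
#'   column per requested statistic.
#' @export
#' @examples
#' dat <- simulate_twin_data(sim_model("1"), n_dz = 3, n_mz = 3, seed = 1)
#' summarize_trajectories(dat)
summarize_trajectories <- function(data,
                                   stats = c("mean", "slope", "intercept", "auc")) {
  stopifnot(inherits(data, "data.frame"))
  stats <- match.arg(stats, several.ok = TRUE)
  if (nrow(data) == 0L) stop("empty phenotype table", call. = FALSE)
  ord <- order(data$pair_id, data$twin, data$age_months)
  data <- data[ord, ]
  key <- interaction(data$pair_id, data$twin, drop = TRUE)
  key <- factor(key, levels = unique(key))  # keep data order for split()

  split_y <- split(data$bmi, key)
  split_t <- split(data$age_months, key)
  ids <- !duplicated(key)
  out <- data.frame(
    pair_id = data$pair_id[ids],
    twin = data$twin[ids],
    zygosity = data$zygosity[ids],
    sex = data$sex[ids],
    genotype = data$genotype[ids],
    stringsAsFactors = FALSE
  )

  if ("mean" %in% stats) {
    out$mean <- unname(vapply(split_y, mean, 0))
  }
  if (any(c("slope", "intercept") %in% stats)) {
    si <- mapply(function(y, t) {
      if (length(unique(t)) < 2L) {
        stop("per-individual regression needs at least 2 distinct ages",
             call. = FALSE)
      }
      b <- stats::cov(t, y) / stats::var(t)
      c(intercept = mean(y) - b * mean(t), slope = b)
    }, split_y, split_t)
    if ("intercept" %in% stats) out$intercept <- unname(si["intercept", ])
    if ("slope" %in% stats) out$slope <- unname(si["slope", ])
  }
  if ("auc" %in% stats) {
    out$auc <- unname(mapply(function(y, t) {
      if (anyDuplicated(t)) {
        stop("duplicated ages within a twin: AUC undefined", call. = FALSE)
      }
      pracma::trapz(t, y)
    }, split_y, split_t))
  }
  rownames(out) <- NULL
  class(out) <- c("twin_summaries", "data.frame")
  out
}

#' @rdname summarize_trajectories
#' @export
mean_summary <- function(data) summarize_trajectories(data, "mean")

#' @rdname summarize_trajectories
#' @export
slope_intercept_summary <- function(data) {
  summarize_trajectories(data, c("slope", "intercept"))
}

#' @rdname summarize_trajectories
#' @export
auc_trapezoid <- function(data) summarize_trajectories(data, "auc")

#' Write per-twin summaries as wide CSV
#'
#' @param x a `twin_summaries` data frame.
#' @param path file path.
#' @export
write_summaries_csv <- function(x, path) {
  stopifnot(inherits(x, "twin_summaries"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
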