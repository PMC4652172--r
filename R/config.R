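#' Read a simulation/evaluation configuration file
#'
#' YAML or JSON configuration selecting a generating model (a built-in
#' preset name via `model`, or an explicit `params` block passed to
#' [twin_params()]), the cohort size (`n_dz`, `n_mz`), an optional visit
#' `schedule` (ages in months), the `methods` to run, `n_reps` and `seed`.
#' Missing fields fall back to the package defaults (226 DZ + 168 MZ
#' pairs, the default schedule, 2000 replicates).
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A list with elements `params` (a [twin_params()] object),
#'   `n_dz`, `n_mz`, `visit_ages`, `methods`, `n_reps`, `seed`, `output`.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  params <- if (!is.null(cfg$model)) {
    sim_model(cfg$model)
  } else if (!is.null(cfg$params)) {
    do.call(twin_params, cfg$params)
  } else {
    stop("config must provide `model` (preset name) or `params`",
         call. = FALSE)
  }
  list(
    params = params,
    n_dz = cfg$n_dz %||% 226L,
    n_mz = cfg$n_mz %||% 168L,
    visit_ages = cfg$schedule %||% c(1, 6, 18, 30, 48, 60),
    methods = cfg$methods %||% "ace_mean",
    n_reps = cfg$n_reps %||% 2000L,
    seed = cfg$seed %||% 1L,
    output = cfg$output %||% "."
  )
}
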