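# Internal helpers: seed handling and argument checks.

# Expand one user-facing seed into `n` independent substream seeds.
# Saves and restores the caller's RNG state so that consuming a substream
# never perturbs an enclosing simulation. Seeds stay below 2^31 - 1.
derive_seeds <- function(seed, n, salt = 0L) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  seed <- as.integer(seed)
  with_preserved_rng({
    set.seed((abs(seed) %% 2147483629L) + 7L * (as.integer(salt) %% 1000L))
    sample.int(2147483646L, n)
  })
}

# Evaluate `expr` with the global RNG state restored afterwards.
with_preserved_rng <- function(expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  expr
}

# Set the RNG for a reproducible block; NULL seed leaves the stream alone.
maybe_set_seed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

stop_if_not_scalar_prob <- function(x, name, open = TRUE) {
  ok <- length(x) == 1L && is.finite(x) &&
    if (open) x > 0 && x < 1 else x >= 0 && x <= 1
  if (!ok) {
    stop(sprintf("`%s` must be a single value in %s, got %s",
                 name, if (open) "(0, 1)" else "[0, 1]",
                 paste(format(x), collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

# Unique per-individual id used for nesting twin within pair.
indiv_id <- function(pair_id, twin) paste0(pair_id, "_", twin)

mc_se_prop <- function(p, n) sqrt(p * (1 - p) / n)
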