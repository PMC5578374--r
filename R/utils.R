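# Internal helpers shared across modules.

# Run `code` with the RNG seeded at `seed`, restoring any prior RNG state on
# exit so library calls never perturb a user's random stream.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Canonical key for an unordered protein pair.
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\x1f")
}

# Two-column character matrix of unordered pairs, canonically ordered.
canonical_pairs <- function(a, b) {
  cbind(pmin(a, b), pmax(a, b))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
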