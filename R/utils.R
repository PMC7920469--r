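## Seed plumbing: all randomness in the package flows through these two
## helpers so that a master seed determines every draw without clobbering
## the caller's RNG state.

withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

## Deterministic child seeds: run/rep i of a procedure seeded with `seed`
## uses childSeeds(seed, k)[i].  Distinct children give independent streams
## for practical purposes while keeping everything reproducible.
childSeeds <- function(seed, k) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, k))
}

.assertMatrix <- function(X, what = "X") {
  if (!is.matrix(X) || !is.numeric(X))
    stop(what, " must be a numeric matrix", call. = FALSE)
  if (anyNA(X)) stop(what, " contains missing values", call. = FALSE)
  invisible(X)
}
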