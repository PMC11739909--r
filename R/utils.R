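# Run code under a temporary RNG state, restoring the caller's stream.
# All stochastic operations in the package route their seeds through this,
# so results are reproducible without clobbering the session RNG.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic child seed from a parent seed and a stage label, kept
# within 32-bit integer range so stages can be re-run independently.
child_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 1009 + h) %% .Machine$integer.max)
}

# sample() with the size-1 gotcha removed
sample_one <- function(x) x[sample.int(length(x), 1L)]
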