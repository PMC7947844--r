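## Seed handling: every stochastic entry point takes an optional seed; when
## given, the RNG state is set for the evaluation and restored afterwards,
## so seeded calls are reproducible without clobbering the caller's stream.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## derive a bounded child seed from a master seed (kept below 2^31)
.child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 1009 + 97 * k) %% 2147483647)
}
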