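## Run code with a locally seeded RNG, restoring global RNG state afterwards
## so simulations are reproducible from their seed argument without touching
## the caller's random stream.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

## Derive a child seed from a base seed and an index, kept inside 32-bit
## integer range.
childSeed <- function(seed, index) {
  as.integer((as.numeric(seed) * 1009 + 97 * as.numeric(index)) %% 2147483647)
}
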