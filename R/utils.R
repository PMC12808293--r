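# internal helpers shared across modules

# run code under a given RNG seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# derive a child seed (< 2^31) from a master seed and an index
child_seed <- function(seed, index) {
  as.integer((as.double(seed) * 1009 + index * 9973) %% 2147483647)
}
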