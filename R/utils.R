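# RNG scoping: seed locally, restore the caller's stream on exit.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  list(restore = function() {
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
}

# Counter-based per-replicate seed stream: replicate r of a run seeded with
# `seed` is reproducible in isolation.  Kept within the 32-bit integer range.
replicate_seed <- function(seed, r) {
  x <- (as.numeric(seed) %% 65011 + 1) * 32749 + 104729 * (as.numeric(r) %% 20011)
  as.integer(x %% 2147483646 + 1)
}
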