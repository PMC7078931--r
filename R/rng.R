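# Seeding helpers. One root seed governs a whole batch or campaign; each
# survey draws from its own substream whose seed is a deterministic function
# of (root seed, counter), so regenerating survey k alone gives the same
# schedule as generating the full batch.

# Lehmer-style mix; result always in [1, 2^31 - 2] so it is a valid set.seed()
# argument on any platform.
substream_seed <- function(seed, index) {
  m <- 2147483647 # 2^31 - 1, prime
  s <- (as.double(seed) %% m) * 48271 + as.double(index) * 69621 + 1
  as.integer(s %% m)
}

# Evaluate `code` under a temporary RNG state; the caller's stream is
# restored afterwards (or removed if none existed).
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
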