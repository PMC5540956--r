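# internal helpers

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards so seeded package functions do not disturb
# the session stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-seed for stream `k` derived from a master seed.
# Linear-congruential style mix kept below 2^31 so it is a valid R seed.
derive_seed <- function(seed, k) {
  s <- (as.double(seed) %% 2147483647) + 1
  k <- as.double(k)
  as.integer((s * 48271 + k * 16807 + 12345) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
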