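`%||%` <- function(x, y) if (is.null(x)) y else x

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so package internals never disturb the
# user's random stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a per-stream child seed from a base seed, keeping the result a
# valid 32-bit integer.
child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(stream) * 104729) %% 2147483647)
}

stop_dim <- function(what, expected, got) {
  stop(sprintf("%s: expected length %d, got %d", what, expected, got),
       call. = FALSE)
}
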