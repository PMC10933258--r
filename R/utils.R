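# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# round-half-up (0.5 always rounds away from zero for positives), unlike
# base round()'s round-half-even
round_half_up <- function(x) floor(x + 0.5)

# derive a stream-specific child seed from a master seed, staying within
# 32-bit integer range
child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 1103 + as.numeric(stream) * 12347) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
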