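# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. Keeps stochastic operations reproducible
# without clobbering the session RNG.
with_local_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministically derive a per-stage seed from one global seed; stays
# within 32-bit integer range.
derive_seed <- function(seed, stage) {
  (as.numeric(seed) * 7919 + stage * 104729) %% 2147483647
}

relative_difference <- function(a, b) {
  d <- max(abs(a - b))
  s <- max(abs(a), abs(b), .Machine$double.xmin)
  d / s
}
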