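# Run expr under a temporary RNG state seeded with `seed`, restoring the
# caller's global RNG afterwards. All stochastic entry points route their
# randomness through this so that a seed argument fully determines output
# without clobbering the user's stream.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("rng_seed must be a single finite number", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministic 31-bit mix of a master seed, a condition key string and a
# replicate index, so every simulation replicate is independently
# reproducible. Plain integer arithmetic in double precision; all
# intermediates stay well below 2^53.
derive_seed <- function(master_seed, key, rep) {
  m <- 2147483629
  h <- 0
  for (v in utf8ToInt(as.character(key))) h <- (h * 131 + v) %% m
  s <- (as.numeric(master_seed) %% m)
  as.integer((((s * 69069) %% m + h) %% m * 69069 + rep) %% m + 1)
}

# Row-wise log-sum-exp of a matrix, tolerating -Inf entries (but not an
# entire row of them).
row_logsumexp <- function(m) {
  mx <- apply(m, 1, max)
  if (any(!is.finite(mx))) {
    stop("degenerate row: all log-weights are -Inf", call. = FALSE)
  }
  mx + log(rowSums(exp(m - mx)))
}
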