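# Internal helpers: seed derivation and RNG scoping.

# Deterministic child seed from a master seed and a stream index.
# Kept below 2^31 so it is always a valid integer seed. The multiplier and
# increment are fixed primes; the exact values are arbitrary but frozen so
# that derived streams are stable across sessions.
derive_seed <- function(master, stream) {
  master <- as.numeric(master) %% 2147483647
  s <- (master * 48271 + as.numeric(stream) * 1000003 + 12345) %% 2147483647
  as.integer(s)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards so library code never perturbs user RNG.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  force(expr)
}

abort_config <- function(msg) {
  abort(msg, class = "spikecollide_config_error")
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort_config(sprintf("`%s` must be a single positive finite number.", name))
  }
  invisible(x)
}

check_non_negative <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0) {
    abort_config(sprintf("`%s` must be a single non-negative finite number.", name))
  }
  invisible(x)
}

# unlist() that returns numeric(0) instead of NULL on empty input
flat_num <- function(x) {
  v <- unlist(x, use.names = FALSE)
  if (is.null(v)) numeric(0) else v
}

# #{v <= x} and #{v < x} for sorted v, vectorised over x.
count_le <- function(x, v) findInterval(x, v)
count_lt <- function(x, v) findInterval(x, v, left.open = TRUE)
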