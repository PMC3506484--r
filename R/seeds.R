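# RNG helpers: every stochastic entry point takes an integer seed and leaves
# the caller's RNG state untouched.

.with_seed <- function(seed, code) {
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

# Deterministic sub-seed streams. Derived seeds stay below 2^31 - 1.
.derive_seeds <- function(seed, n) {
  .with_seed(seed, sample.int(2147483646L, n))
}

# Mix a master seed with an integer key (e.g. a data fingerprint) into a new
# valid seed. Uses double arithmetic to avoid integer overflow.
.mix_seed <- function(seed, key) {
  v <- (as.double(seed) * 48271 + as.double(key) * 16807 + 12345) %% 2147483647
  as.integer(v) + 1L
}

# Content fingerprint of a numeric matrix: equal matrices get equal keys, so
# seeds attached to a data stratum travel with the stratum (this is what
# makes the case/control swap antisymmetry of the U statistic exact).
.data_key <- function(M) {
  M <- as.matrix(M)
  s <- sum(M, na.rm = TRUE) + 7 * sum(M * M, na.rm = TRUE)
  as.integer((abs(s) * 997 + nrow(M) * 131 + ncol(M) * 17) %% 2147483647)
}
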