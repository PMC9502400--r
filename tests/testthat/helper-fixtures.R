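# Shared fixtures, built in code.

# A linearly separable toy fingerprint set: actives carry a block of
# signature bits that inactives never have, on top of random background.
make_separable_toy <- function(n_per_class = 30, n_bits = 64, n_signal = 12,
                               seed = 42) {
  withr::with_seed(seed, {
    X <- matrix(rbinom(2 * n_per_class * n_bits, 1, 0.15), 2 * n_per_class)
    X[seq_len(n_per_class), seq_len(n_signal)] <- 1L
    X[n_per_class + seq_len(n_per_class), seq_len(n_signal)] <- 0L
    list(X = X,
         y = rep(c("ACTIVE", "INACTIVE"), each = n_per_class))
  })
}

# Brute-force Tanimoto of two 0/1 vectors (independent of the package path).
brute_tanimoto <- function(a, b) {
  c_ <- sum(a == 1 & b == 1)
  u <- sum(a == 1) + sum(b == 1) - c_
  if (u == 0) 1 else c_ / u
}

# A small shared benchmark so expensive fixtures are built once per run.
small_benchmark <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- make_benchmark(benchmark_spec(n_compounds = 120, seed = 7))
    }
    cache
  }
})
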