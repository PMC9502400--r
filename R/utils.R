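#' @keywords internal
"_PACKAGE"

# Deterministic integer hashing used by all hashed fingerprint families.
# Polynomial rolling hash over a vector of non-negative integers, modulo a
# Mersenne prime. All arithmetic stays below 2^53 so results are exact in
# doubles and identical across platforms.
.hash_ints <- function(x, mod = 2147483647) {
  h <- 5381
  for (v in x) {
    h <- (h * 33 + v + 1) %% mod
  }
  h
}

# Vectorised variant: hash each row of an integer matrix.
.hash_rows <- function(m, mod = 2147483647) {
  h <- rep(5381, nrow(m))
  for (j in seq_len(ncol(m))) {
    h <- (h * 33 + m[, j] + 1) %% mod
  }
  h
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards, so package functions are deterministic without
# clobbering the user's random stream.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a master seed and a stream index; stays < 2^31.
.child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + index * 16807) %% 2147483399) + 1L
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
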