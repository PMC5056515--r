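# Internal helpers shared across modules.

# Adjusted Rand index between two labelings (Hubert & Arabie 1985).
# Implemented here because no installed package exports it.
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_i * sum_j / comb2(n)
  max_index <- (sum_i + sum_j) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# FNV-1a 32-bit hash of a character scalar, reported as 8 hex digits.
# Used to stamp output files with a config fingerprint; not cryptographic.
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  prime <- 16777619
  for (b in bytes) {
    # xor only touches the low byte; multiply mod 2^32 in two 16-bit limbs
    # to stay within double precision
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (((h1 * prime) %% 65536) * 65536 + h0 * prime) %% 4294967296
  }
  sprintf("%08x", h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Seed derived from a base seed and a stream label, kept within 32-bit range.
derive_seed <- function(seed, stream) {
  (as.integer(seed) + 1000003L * as.integer(stream)) %% 2147483647L
}
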