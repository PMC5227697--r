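#' Half-up rounding
#'
#' Rounds half-way cases away from zero (base [round()] rounds to even),
#' matching how summary-table percentages are conventionally printed.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
roundHalfUp <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# all permutations of 1..n as an n! x n matrix (n small; used for exact
# Mantel p values)
allPermutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- allPermutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (k in seq_len(n)) {
    block <- cbind(k, ifelse(sub >= k, sub + 1L, sub))
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

# Hamming distance between two sequences (mismatches over the shorter
# length plus the length difference)
hammingDistance <- function(a, b) {
  cpp_pairwise_hamming(a, b)
}

# deterministic seed derivation that stays inside 32-bit integer range
deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% .Machine$integer.max)
}
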