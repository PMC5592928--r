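# Independent oracles used to validate the package implementations.
# These are deliberately naive (quadratic DP, exhaustive enumeration,
# direct pmf summation) and share no code with the package.

# Brute-force affine-gap local alignment (Gotoh), gap of length L costing
# open + L * extend.
sw_oracle <- function(a, b, mat, open = 11, extend = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  if (n == 0 || m == 0) return(0)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)
  Iy <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      Ix[i, j] <- max(M[i - 1, j] - (open + extend), Ix[i - 1, j] - extend)
      Iy[i, j] <- max(M[i, j - 1] - (open + extend), Iy[i, j - 1] - extend)
      s <- mat[A[i - 1], B[j - 1]]
      M[i, j] <- max(0, s + max(M[i - 1, j - 1], Ix[i - 1, j - 1],
                                Iy[i - 1, j - 1]))
      best <- max(best, M[i, j])
    }
  }
  best
}

# Exact hypergeometric upper tail by direct pmf summation.
hyper_tail_oracle <- function(k, K, N, n) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Exhaustive PWM p-value: enumerate every word of the motif's width over
# the 20 amino acids, using the same integer discretization as the
# implementation (1/1000 bit bins) so ties land on the same side.
pwm_p_oracle <- function(pwm, bg, s_obs_int) {
  aa <- colnames(pwm$scores)
  si <- round(pwm$scores / 0.001)
  words <- expand.grid(rep(list(seq_len(20)), pwm$width))
  tot <- 0
  for (r in seq_len(nrow(words))) {
    idx <- as.integer(words[r, ])
    s <- sum(si[cbind(seq_len(pwm$width), idx)])
    if (s >= s_obs_int) tot <- tot + prod(bg[aa[idx]])
  }
  tot
}

# Adjusted Rand index (mclust).
ari <- function(x, y) mclust::adjustedRandIndex(x, y)

# BLOSUM62 via the package-internal accessor route is off limits for the
# oracle; load it directly from Biostrings.
blosum62_oracle <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <<- e$BLOSUM62
    }
    m
  }
})
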