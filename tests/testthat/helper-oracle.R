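# Independent brute-force Smith-Waterman with affine gaps (Gotoh three-state
# DP, no optimizations). Written from first principles as a reference oracle;
# deliberately shares no code with the package's alignment path.
# Gap of length L costs open + (L - 1) * extend.
sw_oracle_score <- function(q, t, scoring) {
  M <- scoring$substitution_matrix
  open <- scoring$gap_open; extend <- scoring$gap_extend
  qv <- strsplit(q, "")[[1]]; tv <- strsplit(t, "")[[1]]
  n <- length(qv); m <- length(tv)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)    # best ending in a match/mismatch or fresh start
  E <- matrix(NEG, n + 1, m + 1)  # best ending in a gap in the query (target consumed)
  F <- matrix(NEG, n + 1, m + 1)  # best ending in a gap in the target
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - open, E[i, j - 1] - extend)
      F[i, j] <- max(H[i - 1, j] - open, F[i - 1, j] - extend)
      diag_in <- max(H[i - 1, j - 1], E[i - 1, j - 1], F[i - 1, j - 1])
      H[i, j] <- max(0, diag_in + M[qv[i - 1], tv[j - 1]])
      best <- max(best, H[i, j], E[i, j], F[i, j])
    }
  }
  best
}

# random protein over the 20 standard residues
random_protein <- function(len) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
               len, replace = TRUE), collapse = "")
}
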