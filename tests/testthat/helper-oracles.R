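# Independent reference implementations used as oracles. Each is written
# as a direct transcription of the definition (loops, closed forms), kept
# deliberately separate from the package's computation paths.

# Conditional HWE probabilities from log-factorials (no recurrence).
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  rare <- min(nA, 2 * n - nA)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  logp <- sapply(hets, function(h) {
    aa <- (rare - h) / 2
    bb <- n - aa - h
    lfactorial(n) - lfactorial(aa) - lfactorial(h) - lfactorial(bb) +
      h * log(2) + lfactorial(nA) + lfactorial(2 * n - nA) - lfactorial(2 * n)
  })
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  sum(p[p <= p[match(n_Aa, hets)] * (1 + 1e-12)])
}

# O(n^2 k) double-loop GRM.
naive_grm <- function(X, p) {
  n <- nrow(X); m <- ncol(X)
  W <- matrix(0, n, m)
  for (j in seq_len(m))
    W[, j] <- (X[, j] - 2 * p[j]) / sqrt(2 * p[j] * (1 - p[j]))
  G <- matrix(0, n, n)
  for (i in seq_len(n)) for (l in seq_len(n))
    G[i, l] <- sum(W[i, ] * W[l, ]) / m
  G
}

# Exhaustive greedy clumping with explicit loops and cor()-based r2.
clump_oracle <- function(summary, panel, p_thresh, window_bp, r2_thresh) {
  mk <- as.character(summary$MarkerName)
  p <- as.numeric(summary[["P-value"]])
  sig <- which(p < p_thresh)
  idx <- match(mk[sig], panel$map$variant_id)
  ord <- order(p[sig], as.numeric(panel$map$chrom[idx]), panel$map$bp[idx])
  taken <- rep(FALSE, length(sig))
  out <- list()
  X <- panel$X; storage.mode(X) <- "double"
  for (j in ord) {
    if (taken[j]) next
    taken[j] <- TRUE
    members <- mk[sig[j]]
    for (l in ord) {
      if (taken[l]) next
      same_chr <- panel$map$chrom[idx[l]] == panel$map$chrom[idx[j]]
      close <- abs(panel$map$bp[idx[l]] - panel$map$bp[idx[j]]) <= window_bp
      if (same_chr && close) {
        r2 <- suppressWarnings(cor(X[, idx[j]], X[, idx[l]])^2)
        if (!is.na(r2) && r2 >= r2_thresh) {
          taken[l] <- TRUE
          members <- c(members, mk[sig[l]])
        }
      }
    }
    out[[length(out) + 1]] <- sort(members)
  }
  out
}
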