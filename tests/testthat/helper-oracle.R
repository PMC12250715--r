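# Independent brute-force re-count of the concordance counters: a direct
# double loop over object pairs, written separately from the package's
# vectorized sign path so the two can be checked against each other.
bruteCounters <- function(xs, ys, tieMode = "unbiased", eps = 0) {
  m <- length(xs)
  sMu <- sNu <- sTie <- 0L
  for (i in seq_len(m - 1L)) {
    for (j in seq.int(i + 1L, m)) {
      dx <- xs[i] - xs[j]
      dy <- ys[i] - ys[j]
      tx <- abs(dx) <= eps
      ty <- abs(dy) <= eps
      if (tx || ty) {
        if (tieMode == "mu_biased" && tx && ty) sMu <- sMu + 1L
        else sTie <- sTie + 1L
      } else if ((dx > 0) == (dy > 0)) {
        sMu <- sMu + 1L
      } else {
        sNu <- sNu + 1L
      }
    }
  }
  c(sMu = sMu, sNu = sNu, sTie = sTie)
}

# Brute-force agreement/disagreement matrices for a whole evaluation matrix.
bruteICrA <- function(ev, tieMode = "unbiased", eps = 0) {
  n <- ncol(ev)
  m <- nrow(ev)
  np <- m * (m - 1) / 2
  mu <- nu <- diag(n)
  nu[] <- 0
  for (k in seq_len(n - 1L)) {
    for (l in seq.int(k + 1L, n)) {
      cnt <- bruteCounters(ev[, k], ev[, l], tieMode, eps)
      mu[k, l] <- mu[l, k] <- cnt[["sMu"]] / np
      nu[k, l] <- nu[l, k] <- cnt[["sNu"]] / np
    }
  }
  list(mu = mu, nu = nu)
}

# Random tie-free evaluation matrix.
randomMatrix <- function(m, n) {
  IndexMatrix(matrix(rnorm(m * n), m, n,
                     dimnames = list(paste0("O", seq_len(m)),
                                     paste0("C", seq_len(n)))))
}

# The published per-block positive-consonance counts (threshold settings
# in rows ordered 0.75, 0.70, 0.67, 0.65, 0.60; blocks in columns).
publishedPerBlockCounts <- function() {
  matrix(c(0,  8,  0, 0,
           1, 10,  0, 1,
           1, 10,  5, 1,
           2, 10,  7, 1,
           5, 10, 11, 4),
         nrow = 5L, byrow = TRUE,
         dimnames = list(c("0.75/0.25", "0.70/0.30", "0.67/0.33",
                           "0.65/0.35", "0.60/0.40"),
                         dockingBlockLabels()))
}
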