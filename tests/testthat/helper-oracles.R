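# Independent oracles used across the suite. These deliberately avoid the
# package's code paths: naive loops, direct formula transcriptions.

# brute-force mutual information over the joint histogram (double loop)
mi_oracle <- function(x, y) {
  n <- length(x)
  s <- 0
  for (a in unique(x)) {
    for (b in unique(y)) {
      pxy <- sum(x == a & y == b) / n
      if (pxy > 0) {
        s <- s + pxy * log(pxy / ((sum(x == a) / n) * (sum(y == b) / n)))
      }
    }
  }
  s
}

# entropy of a discrete vector, naive
entropy_oracle <- function(x) {
  p <- as.numeric(table(x)) / length(x)
  -sum(p * log(p))
}

# spreadsheet-style recomputation of the counting-based risk stage:
# per-factor level counts tallied cell by cell, then the stated formulas
risk_oracle <- function(ratings) {
  n <- nrow(ratings)
  lev <- function(r) if (r <= 2) "low" else if (r == 3) "medium" else "high"
  groups <- list(core = 1:4, external = 5:8)
  out <- list()
  for (j in 1:8) {
    grp <- if (j <= 4) groups$core else groups$external
    for (l in c("low", "medium", "high")) {
      cnt_col <- 0
      for (i in 1:n) if (lev(ratings[i, j]) == l) cnt_col <- cnt_col + 1
      cnt_grp <- 0
      for (g in grp) {
        for (i in 1:n) if (lev(ratings[i, g]) == l) cnt_grp <- cnt_grp + 1
      }
      prior <- cnt_grp / (4 * n)
      likelihood <- cnt_col / (6 * n)
      inverse <- 1 - likelihood
      marginal <- prior * likelihood + (1 - prior) * inverse
      posterior <- if (marginal == 0) NA else prior * likelihood / marginal
      out[[paste0("X", j, ".", l)]] <- posterior
    }
  }
  # all-cause: pooled share of all 8 columns as both prior and likelihood
  for (l in c("low", "medium", "high")) {
    cnt <- 0
    for (j in 1:8) for (i in 1:n) if (lev(ratings[i, j]) == l) cnt <- cnt + 1
    p <- cnt / (8 * n)
    marginal <- p * p + (1 - p) * (1 - p)
    out[[paste0("all.", l)]] <- if (marginal == 0) NA else p * p / marginal
  }
  unlist(out)
}

# random valid panel matrix
random_ratings <- function(n, seed, k = 8) {
  set.seed(seed)
  matrix(sample(1:5, n * k, replace = TRUE), n, k,
         dimnames = list(NULL, paste0("X", 1:k)))
}

expected_sv <- c(X1 = 0.0549, X2 = 0.1471, X3 = 0.2411, X4 = 0.2800,
                 X5 = 0.0549, X6 = 0.2411, X7 = 0.0511, X8 = 0.3881)
expected_oi <- c(X1 = 0.1831, X2 = 0.2719, X3 = 0.3665, X4 = 0.4051,
                 X5 = 0.1795, X6 = 0.3657, X7 = 0.1757, X8 = 0.5106)
expected_as <- c(X1 = 6L, X2 = 5L, X3 = 3L, X4 = 2L, X5 = 7L, X6 = 4L,
                 X7 = 8L, X8 = 1L)
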