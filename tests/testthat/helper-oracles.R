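# Independent brute-force oracles for the statistical primitives. These
# stay deliberately naive: different formulas and different code paths
# from the implementations they check.

# Naive step-up FDR adjustment, straight from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- 1
  for (k in m:1) {
    i <- ord[k]
    running <- min(running, p[i] * m / k)
    adj[i] <- running
  }
  pmin(adj, 1)
}

# Exact two-sided Mann-Whitney p by enumerating group labelings, computing
# U from pairwise comparisons (not rank sums).
oracle_mann_whitney <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  n <- length(pooled)
  u_of <- function(x, y) {
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  obs <- u_of(a, b)
  labelings <- utils::combn(n, n1)
  us <- apply(labelings, 2, function(idx) {
    u_of(pooled[idx], pooled[-idx])
  })
  eps <- 1e-9
  min(1, 2 * min(mean(us <= obs + eps), mean(us >= obs - eps)))
}

# Exact two-sided Wilcoxon signed-rank p by looping over all sign vectors
# with bit arithmetic.
oracle_wilcoxon <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  obs <- sum(r[d > 0])
  ws <- numeric(2^n)
  for (mask in 0:(2^n - 1)) {
    w <- 0
    for (bit in seq_len(n)) {
      if (bitwAnd(mask, bitwShiftL(1L, bit - 1L)) != 0) w <- w + r[bit]
    }
    ws[mask + 1] <- w
  }
  eps <- 1e-9
  min(1, 2 * min(mean(ws <= obs + eps), mean(ws >= obs - eps)))
}

# Character-by-character scanner for composition counts (no rle, no regex).
oracle_composition <- function(seq, min_run = 2) {
  ch <- strsplit(seq, "")[[1]]
  counts <- c(A = 0, C = 0, G = 0, T = 0)
  runs <- 0
  g_len <- 0
  for (x in ch) {
    counts[x] <- counts[x] + 1
    if (x == "G") {
      g_len <- g_len + 1
      if (g_len == min_run) runs <- runs + 1
    } else {
      g_len <- 0
    }
  }
  list(n_A = unname(counts["A"]), n_C = unname(counts["C"]),
       n_G = unname(counts["G"]), n_T = unname(counts["T"]),
       n_GG_runs = runs)
}

# Direct-formula Pearson distance.
oracle_pearson_distance <- function(mat) {
  m <- ncol(mat)
  d <- matrix(0, m, m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      x <- mat[, i]; y <- mat[, j]
      r <- sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
      d[i, j] <- 1 - r
    }
  }
  diag(d) <- 0
  d
}
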