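# Independent brute-force oracles for the statistical primitives. These
# enumerate or apply textbook formulas directly and never call the package
# functions they check.

oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; c1 <- a + c_; N <- a + b + c_ + d
  xs <- max(0, c1 - (N - r1)):min(r1, c1)
  probs <- vapply(xs, function(x)
    choose(r1, x) * choose(N - r1, c1 - x) / choose(N, c1), numeric(1))
  obs <- probs[xs == a]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

oracle_hyper_tail <- function(k, K, n, N) {
  js <- k:min(K, n)
  sum(vapply(js, function(j)
    choose(K, j) * choose(N - K, n - j) / choose(N, n), numeric(1)))
}

# Exact two-sided rank-sum p by enumerating all assignments of pooled
# ranks to the first sample (no ties assumed).
oracle_wilcoxon_p <- function(x, y) {
  m <- length(x); n <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2  # Mann-Whitney U of x
  sets <- utils::combn(m + n, m)
  ws <- apply(sets, 2, function(idx) sum(r[idx])) - m * (m + 1) / 2
  p_le <- mean(ws <= w_obs)
  p_ge <- mean(ws >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

oracle_hochberg <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    vals <- vapply(i:m, function(j) (m - j + 1) * p[o[j]], numeric(1))
    adj[o[i]] <- min(1, min(vals))
  }
  adj
}

oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    vals <- vapply(i:m, function(j) m / j * p[o[j]], numeric(1))
    adj[o[i]] <- min(1, min(vals))
  }
  adj
}

# Brute-force per-base mean coverage of one region.
oracle_region_mean <- function(region, track) {
  bases <- rep(0, region$end - region$start)
  steps <- track[track$chrom == region$chrom, , drop = FALSE]
  for (i in seq_len(nrow(steps))) {
    s <- max(steps$start[i], region$start); e <- min(steps$end[i], region$end)
    if (e > s) bases[(s - region$start + 1):(e - region$start)] <- steps$depth[i]
  }
  mean(bases)
}
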