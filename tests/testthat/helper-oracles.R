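# Independent oracles used across tests. These deliberately avoid the code
# paths they check: hypergeometric tails are enumerated from log-binomial
# coefficients, BH is re-derived from the step-up definition, and interval
# unions are computed on explicit base sets.

# Exact Fisher p for the 2x2 table matrix(c(a, b, c, d), 2, 2) by
# enumerating the conditional hypergeometric distribution. Column margins
# (a+b) and (c+d) are fixed; x ranges over feasible top-left values.
oracle_fisher_2x2 <- function(a, b, c, d, alternative = "two.sided") {
  m1 <- a + b; m2 <- c + d; k <- a + c
  lo <- max(0, k - m2); hi <- min(k, m1)
  x <- lo:hi
  logp <- lchoose(m1, x) + lchoose(m2, k - x) - lchoose(m1 + m2, k)
  p <- exp(logp)
  p_obs <- p[x == a]
  if (alternative == "two.sided") sum(p[p <= p_obs * (1 + 1e-7)])
  else sum(p[x >= a])                      # "greater": enrichment of a
}

# Step-up BH re-implementation via sorting and a right-to-left minimum.
oracle_bh <- function(p) {
  m <- length(p)
  ps <- sort(p)
  adj <- ps * m / seq_len(m)
  if (m > 1) for (i in (m - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  adj <- pmin(adj, 1)
  adj[rank(p, ties.method = "first")]
}

# Base-set union of intervals on one coordinate system (brute force).
oracle_merge <- function(x) {
  out <- NULL
  for (ch in sort(unique(x$chrom))) {
    xi <- x[x$chrom == ch, ]
    bases <- sort(unique(unlist(Map(function(s, e) seq(s, e - 1), xi$start, xi$end))))
    if (length(bases) == 0) next
    brk <- c(0, which(diff(bases) > 1), length(bases))
    for (j in seq_len(length(brk) - 1)) {
      seg <- bases[(brk[j] + 1):brk[j + 1]]
      out <- rbind(out, data.frame(chrom = ch, start = min(seg), end = max(seg) + 1))
    }
  }
  out
}

# Exact two-sided rank-sum p-value by full enumeration of group assignments
# (feasible for small samples only).
oracle_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  w_obs <- sum(rank(pooled)[seq_len(na)])
  combs <- utils::combn(n, na)
  w_all <- apply(combs, 2, function(idx) sum(rank(pooled)[idx]))
  mu <- na * (n + 1) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

skip_free_seed <- 20260930  # fixed seed for property-style loops
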