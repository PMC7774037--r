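# Independent brute-force oracles, written against the stated definitions
# (not against the package implementation).

# TMM factors by explicit sort-based trimming and a naive weighted mean.
oracle_tmm <- function(counts, ref, trim_m = 0.30, trim_a = 0.05) {
  N <- colSums(counts)
  f <- numeric(ncol(counts))
  for (s in seq_len(ncol(counts))) {
    cs <- counts[, s]
    cr <- counts[, ref]
    pos <- which(cs > 0 & cr > 0)
    ps <- cs[pos] / N[s]
    pr <- cr[pos] / N[ref]
    M <- log2(ps / pr)
    A <- 0.5 * log2(ps * pr)
    w <- (N[s] - cs[pos]) / (N[s] * cs[pos]) +
      (N[ref] - cr[pos]) / (N[ref] * cr[pos])
    n <- length(pos)
    km <- floor(trim_m * n)
    ka <- floor(trim_a * n)
    drop_m <- c(order(M)[seq_len(km)], order(M)[n + 1 - seq_len(km)])
    drop_a <- c(order(A)[seq_len(ka)], order(A)[n + 1 - seq_len(ka)])
    keep <- setdiff(seq_len(n), union(if (km > 0) drop_m else integer(0),
                                      if (ka > 0) drop_a else integer(0)))
    num <- 0; den <- 0
    for (g in keep) {
      num <- num + M[g] / w[g]
      den <- den + 1 / w[g]
    }
    f[s] <- 2^(num / den)
  }
  f / exp(mean(log(f)))
}

# Two-sided exact binomial test p-value by direct enumeration (the phi = 0
# limit of the exact NB test with equal group sizes).
oracle_binom_two_sided <- function(sumA, sumB, prob = 0.5) {
  total <- sumA + sumB
  probs <- dbinom(0:total, total, prob)
  sum(probs[probs <= probs[sumA + 1] * (1 + 1e-12)])
}

# Hypergeometric upper tail by direct enumeration over choose() terms.
oracle_hyper_upper <- function(N, K, n, k) {
  a <- k:min(K, n)
  sum(choose(K, a) * choose(N - K, n - a)) / choose(N, n)
}

# BH step-up by the naive quadratic definition q_(i) = min_{j>=i} p_(j)*m/j.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(p[o][i:m] * m / (i:m)))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}
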