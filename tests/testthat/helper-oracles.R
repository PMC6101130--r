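# Independent oracles used by the tests; deliberately naive
# implementations that do not share code with the package.

# Exact two-sided Mann-Whitney P by full enumeration of all C(n1+n2, n1)
# group labelings (no ties assumed).
mw_enumeration_oracle <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  u_all <- apply(combos, 2L, function(idx) {
    sum(r[idx]) - n1 * (n1 + 1) / 2
  })
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  list(U = u_obs, p_value = min(1, 2 * min(p_le, p_ge)))
}

# Brute-force cumulative diversity: sort counts descending (gene id as
# tiebreak) and sum the top k.
diversity_oracle <- function(counts, ranks) {
  df <- data.frame(id = names(counts), n = as.numeric(counts))
  df <- df[order(-df$n, df$id), ]
  vapply(ranks, function(k) {
    if (k >= nrow(df)) 1 else sum(df$n[seq_len(k)]) / sum(df$n)
  }, 0)
}

# Linear-interpolation percentile selection done longhand for the
# upper-middle-quartile rule.
umq_oracle <- function(counts) {
  expressed <- counts[counts > 0]
  q50 <- unname(quantile(expressed, 0.5, type = 7))
  q75 <- unname(quantile(expressed, 0.75, type = 7))
  if (q50 == q75) names(expressed)[expressed == q50] else
    names(expressed)[expressed >= q50 & expressed < q75]
}
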