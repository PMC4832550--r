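# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Monte-Carlo rejection rate of a two-sided pooled-variance t-test,
# n per group, true mean difference d, per-group SD `sd`.
mc_two_sample_reject <- function(d, n, alpha = 0.05, B = 10000, sd = 1) {
  x <- matrix(stats::rnorm(n * B, mean = d, sd = sd), nrow = n)
  y <- matrix(stats::rnorm(n * B, mean = 0, sd = sd), nrow = n)
  mx <- colMeans(x); my <- colMeans(y)
  vx <- apply(x, 2, stats::var); vy <- apply(y, 2, stats::var)
  sp2 <- ((n - 1) * vx + (n - 1) * vy) / (2 * n - 2)
  tstat <- (mx - my) / sqrt(sp2 * 2 / n)
  mean(abs(tstat) > stats::qt(1 - alpha / 2, 2 * n - 2))
}

# Exact two-sided Mann-Whitney p-value by full enumeration of group
# assignments (no ties assumed). Matches the convention two-sided p =
# min(1, 2 * min(P(U <= u), P(U >= u))).
exact_mw_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  z <- c(x, y)
  r <- rank(z)
  u_of <- function(idx) sum(r[idx]) - nx * (nx + 1) / 2
  u_obs <- u_of(seq_len(nx))
  all_u <- apply(utils::combn(nx + ny, nx), 2, u_of)
  p_lo <- mean(all_u <= u_obs)
  p_hi <- mean(all_u >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Classical pooled-variance t-test p-value straight from stats::t.test.
oracle_t_p <- function(x, y) {
  stats::t.test(x, y, var.equal = TRUE)$p.value
}
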