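# Independent oracle implementations used to cross-check the package.
# Deliberately written with different primitives than the implementation.

# All-window Hamming scan via character splitting.
oracle_find_pattern <- function(seq, pattern, max_mm) {
  s <- strsplit(seq, "")[[1]]
  p <- strsplit(pattern, "")[[1]]
  np <- length(p)
  out <- integer(0)
  for (i in seq_len(length(s) - np + 1L)) {
    if (sum(s[i:(i + np - 1L)] != p) <= max_mm) out <- c(out, i)
  }
  out
}

# Hypergeometric enumeration with choose() for a 2x2 two-sided Fisher p.
oracle_fisher_p <- function(a, b, c, d) {
  n <- a + b + c + d
  r <- a + b
  cc <- a + c
  ks <- max(0, cc - (n - r)):min(r, cc)
  pr <- choose(r, ks) * choose(n - r, cc - ks) / choose(n, cc)
  sum(pr[pr <= pr[ks == a] * (1 + 1e-7)])
}

# Direct Benjamini-Hochberg step-up formula.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  pmin(adj, 1)[order(o)]
}

# Exact two-sided Wilcoxon p by enumerating group assignments; the rank-sum
# statistic is recomputed from pairwise comparisons, not shared ranks.
oracle_wilcox_p <- function(x, y) {
  n1 <- length(x); vals <- c(x, y); n <- length(vals)
  stat <- function(idx) {
    xs <- vals[idx]; ys <- vals[-idx]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "==")) +
      n1 * (n1 + 1) / 2
  }
  w_obs <- stat(seq_len(n1))
  all_w <- apply(utils::combn(n, n1), 2, stat)
  eps <- 1e-9
  min(1, 2 * min(mean(all_w <= w_obs + eps), mean(all_w >= w_obs - eps)))
}

# Dense full-SVD leverage.
oracle_leverage <- function(mat, k) {
  u <- svd(mat)$u[, seq_len(k), drop = FALSE]
  rowSums(u^2)
}

# Adjusted Rand index between two labelings (pair-counting formula).
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  exp_idx <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == exp_idx) return(1)
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}
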