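# Brute-force oracle for the exact two-sided rank-sum p-value: enumerate
# every assignment of n_x of the pooled ranks to group x. Independent of
# the package's pwilcox-based implementation.
exact_ranksum_oracle <- function(n_x, n_y) {
  n <- n_x + n_y
  sets <- utils::combn(n, n_x)
  u <- colSums(matrix(seq_len(n)[sets], nrow = n_x)) -
    n_x * (n_x + 1) / 2
  list(u = u, p = vapply(u, function(ui)
    min(1, 2 * min(mean(u <= ui), mean(u >= ui))), numeric(1)))
}

# Independently coded multiple-testing oracles (scale / step-up).
bonferroni_oracle <- function(p) pmin(1, p * length(p))
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  stepped <- p[o] * m / seq_len(m)
  adj_sorted <- pmin(1, rev(cummin(rev(stepped))))
  adj <- numeric(m)
  adj[o] <- adj_sorted
  adj
}
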