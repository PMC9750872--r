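# Independent oracles used across tests. These deliberately avoid the code
# paths they check.

# Exhaustive two-sided Mann-Whitney p by enumerating every assignment of the
# pooled ranks to the first group. Tie-free data only.
mw_enum_p <- function(x, y) {
  m <- length(x)
  n <- length(y)
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combs <- utils::combn(m + n, m)
  u_null <- colSums(matrix(seq_len(m + n)[combs], nrow = m)) -
    m * (m + 1) / 2
  p <- 2 * min(mean(u_null <= u_obs), mean(u_null >= u_obs))
  min(p, 1)
}

# Null U distribution for group sizes (m, n), by the same enumeration.
mw_null_u <- function(m, n) {
  combs <- utils::combn(m + n, m)
  colSums(matrix(seq_len(m + n)[combs], nrow = m)) - m * (m + 1) / 2
}
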