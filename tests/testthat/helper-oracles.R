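# Independent brute-force oracles shared by the unit and acceptance suites.

# --- oracles ---------------------------------------------------------------

# Exact two-sided Mann-Whitney p by enumerating all C(n1+n2, n1) labelings.
mw_enumeration_oracle <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_stat <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  obs <- u_stat(seq_len(n1))
  mu <- n1 * (length(y)) / 2
  splits <- utils::combn(length(pooled), n1)
  us <- apply(splits, 2, u_stat)
  mean(abs(us - mu) >= abs(obs - mu) - 1e-9)
}

# Step-up BH by direct definition.
bh_oracle <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= q * seq_len(m) / m)
  rejected <- logical(m)
  if (length(k)) rejected[o[seq_len(max(k))]] <- TRUE
  rejected
}

# Two-sided Fisher p by hypergeometric enumeration over fixed margins.
fisher_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(xs, r1, r2, c1)
  obs <- dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

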