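# Independent brute-force oracles; kept deliberately naive and separate from
# the package's code paths.

# Exact one-sided rank-sum p by enumerating every group assignment with a
# bitmask (combined n <= ~14). Mid-ranks for ties; alternative "x greater".
brute_rank_sum_p <- function(x, y) {
  n1 <- length(x)
  n <- n1 + length(y)
  r <- rank(c(x, y))
  obs <- sum(r[seq_len(n1)])
  count <- 0L
  total <- 0L
  for (mask in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(mask))[1:n]
    if (sum(bits) != n1) next
    total <- total + 1L
    if (sum(r[bits == 1L]) >= obs - 1e-9) count <- count + 1L
  }
  count / total
}

# Literal Benjamini-Hochberg step-up definition:
# q_(i) = min over j >= i of min(1, p_(j) * m / j), in input order.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  qs <- numeric(m)
  for (i in seq_len(m)) qs[i] <- min(1, min(ps[i:m] * m / (i:m)))
  q <- numeric(m)
  q[o] <- qs
  q
}
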