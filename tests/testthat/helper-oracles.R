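# Independent brute-force oracles, deliberately kept apart from the package
# implementation.

# Uniform-leaf-split (Yule) process tracking leaf depths only: pick a
# uniform random leaf, replace it by two leaves one level deeper.
yule_depths_oracle <- function(n_leaves) {
  d <- 0L
  while (length(d) < n_leaves) {
    i <- sample.int(length(d), 1L)
    d <- c(d[-i], d[i] + 1L, d[i] + 1L)
  }
  d
}

# One fragmentation run written independently of the package: returns the
# within-run sd of log leaf volumes.
sigma_oracle <- function(n, mu = 0, noise = 0.1) {
  lv <- 0
  while (length(lv) < n) {
    k <- length(lv)
    w <- exp(mu * (lv - max(lv)))
    i <- sample.int(k, 1L, prob = w / sum(w))
    r <- rnorm(1, 1, noise)
    while (r <= 0.02 || r >= 1.98) r <- rnorm(1, 1, noise)
    old <- lv[i]
    lv[i] <- old + log(r / 2)
    lv <- c(lv, old + log((2 - r) / 2))
  }
  sd(lv)
}
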