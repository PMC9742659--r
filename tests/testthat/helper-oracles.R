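# Independent oracles and small builders shared across tests.

# A tiny 3-stage network used where full-size training would be wasteful.
tiny_cfg <- function() {
  u2net_config(stages = list(
    rsu_config(2, 1, 2, 3),
    rsu_config(1, 3, 2, 3),
    rsu_config(2, 3, 2, 3, dilated = TRUE)))
}

rand_slices <- function(n, size = 8, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) matrix(runif(size * size), size, size))
}

# Brute-force SSIM: explicit loop over valid window positions with Gaussian
# weights, written independently of the convolution-based implementation.
ssim_bruteforce <- function(pred, ref, L = 5, win = 11L, sigma = 1.5) {
  r <- (win - 1L) %/% 2L
  g1 <- exp(-0.5 * ((-r:r) / sigma)^2)
  K <- outer(g1, g1); K <- K / sum(K)
  C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2
  H <- nrow(pred); W <- ncol(pred)
  vals <- c()
  for (i in (r + 1):(H - r)) {
    for (j in (r + 1):(W - r)) {
      wp <- pred[(i - r):(i + r), (j - r):(j + r)]
      wr <- ref[(i - r):(i + r), (j - r):(j + r)]
      m1 <- sum(K * wp); m2 <- sum(K * wr)
      v1 <- sum(K * wp^2) - m1^2
      v2 <- sum(K * wr^2) - m2^2
      cv <- sum(K * wp * wr) - m1 * m2
      vals <- c(vals, ((2 * m1 * m2 + C1) * (2 * cv + C2)) /
                  ((m1^2 + m2^2 + C1) * (v1 + v2 + C2)))
    }
  }
  mean(vals)
}

# Exact two-sided Mann-Whitney p-value by enumerating every assignment of the
# pooled observations to the two groups (no ties assumed).
mann_whitney_exact <- function(a, b) {
  pool <- c(a, b)
  n <- length(a)
  combs <- utils::combn(length(pool), n)
  u_of <- function(idx) {
    x <- pool[idx]; y <- pool[-idx]
    sum(outer(x, y, ">")) # U statistic for the first group
  }
  u_obs <- u_of(seq_len(n))
  us <- apply(combs, 2, u_of)
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  min(p, 1)
}

# Closed-form full-batch gradient of mean((X theta - y)^2) for the linear toy.
linear_grad <- function(theta, X, y) {
  as.numeric(2 * crossprod(X, X %*% theta - y) / length(y))
}

# A small deterministic disc attenuation map.
disc_mu <- function(n, px, radius_mm, mu) {
  co <- (seq_len(n) - (n + 1) / 2) * px
  xg <- matrix(co, n, n); yg <- matrix(co, n, n, byrow = TRUE)
  m <- matrix(0, n, n)
  m[xg^2 + yg^2 <= radius_mm^2] <- mu
  m
}
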