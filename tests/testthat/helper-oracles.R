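# Independent brute-force references used to check the package's
# statistics. Kept deliberately naive and separate from the implementation.

oracle_kurtosis <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  m2 <- sum((x - m)^2) / n
  m4 <- sum((x - m)^4) / n
  m4 / m2^2
}

oracle_pcf <- function(r, n_osc) {
  n_osc * (sum(r^2) / length(r) - (sum(r) / length(r))^2)
}

# biased single-lag Pearson autocorrelation, direct sums
oracle_acf_lag <- function(x, lag) {
  n <- length(x)
  m <- mean(x)
  num <- sum((x[1:(n - lag)] - m) * (x[(1 + lag):n] - m))
  den <- sum((x - m)^2)
  num / den
}

# Spearman rho from explicit ranks
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# naive DFA-1: explicit per-box lm() detrending
oracle_dfa <- function(x, box_sizes) {
  prof <- cumsum(x - mean(x))
  fl <- sapply(box_sizes, function(b) {
    nb <- length(prof) %/% b
    res2 <- sapply(seq_len(nb), function(k) {
      seg <- prof[((k - 1) * b + 1):(k * b)]
      tt <- seq_len(b)
      r <- stats::residuals(stats::lm(seg ~ tt))
      mean(r^2)
    })
    sqrt(mean(res2))
  })
  unname(coef(stats::lm(log(fl) ~ log(box_sizes)))[2])
}

# fractional Gaussian noise via Davies-Harte circulant embedding
make_fgn <- function(n, H, seed = 1) {
  withr::with_seed(seed, {
    k <- 0:(n - 1)
    g <- 0.5 * (abs(k - 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k + 1)^(2 * H))
    circ <- c(g, 0, rev(g[-1]))
    lam <- Re(stats::fft(circ))
    lam[lam < 0] <- 0
    m <- length(circ)
    zr <- stats::rnorm(m); zi <- stats::rnorm(m)
    w <- sqrt(lam / (2 * m)) * complex(real = zr, imaginary = zi)
    Re(stats::fft(w))[1:n] * sqrt(2)
  })
}

# small fast default topology for simulation tests
test_topology <- function(n = 30, links = 90, seed = 7) {
  generate_topology("random", n, links, seed = seed)
}
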