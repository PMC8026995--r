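# Independent brute-force oracles, deliberately written as straight-line
# re-implementations so the fast package paths are checked against them.

oracle_rs <- function(block) {
  y <- block - sum(block) / length(block)
  z <- cumsum(y)
  s <- sqrt(sum(y^2) / length(block))
  (max(z) - min(z)) / s
}

oracle_sampen <- function(x, m, r) {
  Nm <- length(x) - m
  A <- 0; B <- 0
  for (i in 1:(Nm - 1)) for (j in (i + 1):Nm) {
    if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) {
      B <- B + 1
      if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1
    }
  }
  if (A == 0) Inf else -log(A / B)
}

oracle_apen <- function(x, m, r) {
  phi <- function(mm) {
    M <- length(x) - mm + 1
    v <- numeric(M)
    for (i in 1:M) {
      cnt <- 0
      for (j in 1:M)
        if (max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)])) <= r)
          cnt <- cnt + 1
      v[i] <- log(cnt / M)
    }
    mean(v)
  }
  phi(m) - phi(m + 1)
}

# Full R/S pipeline on explicit block sizes: mean R/S per size via per-block
# arithmetic, then log10-log10 least squares.
oracle_hurst_empirical <- function(x, sizes) {
  lrs <- sapply(sizes, function(n) {
    m <- length(x) %/% n
    vals <- sapply(1:m, function(i) oracle_rs(x[((i - 1) * n + 1):(i * n)]))
    log10(mean(vals))
  })
  unname(coef(lm(lrs ~ log10(sizes)))[2])
}

oracle_expected_rs <- function(n) {
  K <- ((n - 1):1) / (1:(n - 1))
  ratio <- (n - 0.5) / n * sum(sqrt(K))
  if (n > 340) ratio / sqrt(0.5 * pi * n)
  else gamma(0.5 * (n - 1)) * ratio / (gamma(0.5 * n) * sqrt(pi))
}

# Average mutual information at one lag via an explicit joint histogram.
oracle_ami <- function(x, tau, n_bins) {
  brk <- seq(min(x), max(x), length.out = n_bins + 1)
  bin <- findInterval(x, brk, rightmost.closed = TRUE, all.inside = TRUE)
  N <- length(x)
  a <- bin[1:(N - tau)]; b <- bin[(tau + 1):N]
  p <- matrix(0, n_bins, n_bins)
  for (k in seq_along(a)) p[a[k], b[k]] <- p[a[k], b[k]] + 1
  p <- p / (N - tau)
  pa <- rowSums(p); pb <- colSums(p)
  tot <- 0
  for (i in 1:n_bins) for (j in 1:n_bins)
    if (p[i, j] > 0) tot <- tot + p[i, j] * log(p[i, j] / (pa[i] * pb[j]))
  tot
}

logistic_series <- function(n, x0 = 0.2) {
  x <- numeric(n); x[1] <- x0
  for (i in 2:n) x[i] <- 4 * x[i - 1] * (1 - x[i - 1])
  x
}

ar1_series <- function(n, phi, seed) {
  set.seed(seed)
  as.numeric(stats::arima.sim(list(ar = phi), n))
}
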