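# Shared fixtures and independent oracles for the test suite.

# small well-formed scan built in code
make_tiny_scan <- function(grid_rows = 2L, grid_cols = 2L, repeats = 1L,
                           n_chan = 8L, seed = 42L) {
  set.seed(seed)
  wn <- seq(100, 3000, length.out = n_chan)
  n <- grid_rows * grid_cols * repeats
  spectral_scan(wn, matrix(runif(n * n_chan, 0, 1000), n, n_chan),
                grid_rows, grid_cols, repeats)
}

# literal per-window double-loop guided filter (independent oracle):
# every pixel k is a window center; window statistics and the final
# coefficient averages use the window clipped to the image.
oracle_guided <- function(p, r, eps) {
  m <- nrow(p); n <- ncol(p)
  a <- matrix(0, m, n); b <- matrix(0, m, n)
  for (ki in 1:m) {
    for (kj in 1:n) {
      w <- p[max(1, ki - r):min(m, ki + r), max(1, kj - r):min(n, kj + r)]
      mu <- mean(w)
      s2 <- mean((w - mu)^2)
      a[ki, kj] <- s2 / (s2 + eps)
      b[ki, kj] <- (1 - a[ki, kj]) * mu
    }
  }
  q <- matrix(0, m, n)
  for (i in 1:m) {
    for (j in 1:n) {
      abar <- mean(a[max(1, i - r):min(m, i + r), max(1, j - r):min(n, j + r)])
      bbar <- mean(b[max(1, i - r):min(m, i + r), max(1, j - r):min(n, j + r)])
      q[i, j] <- abar * p[i, j] + bbar
    }
  }
  q
}

# literal per-pixel loop implementation of the ratio-reset Retinex
# (ratio, product, reset, average; bidirectional sweeps; repeated
# step-halving schedule) — written scalar-by-scalar, independent of the
# vectorized implementation.
oracle_retinex <- function(img, cycles = 4L) {
  m <- nrow(img); n <- ncol(img)
  rng <- range(img)
  if (rng[1] == rng[2]) return(matrix(0, m, n))
  d <- img * (255 / rng[2]) + 1
  constant <- log10(max(d))
  L <- matrix(constant, m, n)
  pair_update <- function(L, ti, tj, fi, fj) {
    est <- L[fi, fj] + log10(d[ti, tj] / d[fi, fj])
    if (est > constant) est <- constant
    (est + L[ti, tj]) / 2
  }
  for (cycle in seq_len(cycles)) {
    h <- max(1, m %/% 2); theta <- max(1, n %/% 2)
    repeat {
      if (h < m) {
        Lnew <- L
        for (i in 1:(m - h)) for (j in 1:n)
          Lnew[i, j] <- pair_update(L, i, j, i + h, j)
        L <- Lnew
        Lnew <- L
        for (i in (h + 1):m) for (j in 1:n)
          Lnew[i, j] <- pair_update(L, i, j, i - h, j)
        L <- Lnew
      }
      if (theta < n) {
        Lnew <- L
        for (i in 1:m) for (j in 1:(n - theta))
          Lnew[i, j] <- pair_update(L, i, j, i, j + theta)
        L <- Lnew
        Lnew <- L
        for (i in 1:m) for (j in (theta + 1):n)
          Lnew[i, j] <- pair_update(L, i, j, i, j - theta)
        L <- Lnew
      }
      if (h == 1 && theta == 1) break
      h <- max(1, h %/% 2); theta <- max(1, theta %/% 2)
    }
  }
  lr <- range(L)
  (L - lr[1]) / (lr[2] - lr[1]) * 255
}

# quiet noiseless phantom spec used by several tests
noiseless_spec <- function(...) {
  phantom_spec(gauss_sigma = 0, shot_scale = 0, salt_prob = 0, ...)
}
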