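#' Ratio-reset Retinex contrast enhancement
#'
#' Iterative ratio-reset Retinex in the log domain.  The working copy of
#' the image is rescaled so its maximum is 255 and offset by +1 (logs need
#' positivity; the pre-scaling makes the result invariant to multiplicative
#' rescaling of the input).  The log-luminance estimate starts at the
#' constant log10(P), P the working maximum.  Each sweep compares pixel
#' pairs a step apart — rows at step `h` (initially floor(m/2)), then
#' columns at step `theta` (initially floor(n/2)), in both directions — and
#' replaces the pixel's estimate by the partner's estimate plus the log
#' intensity ratio `log10(d[i]/d[partner])` (ratio and product steps),
#' resetting any estimate exceeding the constant back to it (reset step).
#' Steps halve (integer floor, minimum 1) until a sweep has run with both
#' steps equal to 1; chaining the partner's estimate propagates brightness
#' relations across the whole image.  The final estimate is affinely
#' stretched to span \[0, 255\].
#'
#' Bright pixels are clamped at the constant and darker pixels settle
#' below it, so the bright-cell / dark-substrate polarity of the peak image
#' is preserved while dark detail is expanded.  Pixel pairs whose partner
#' falls outside the image are skipped (no wraparound).  A constant image
#' returns all zeros (the stretch is degenerate).
#'
#' One pass of the halving schedule only propagates relations part of the
#' way (the classic halo effect); the schedule is therefore repeated
#' `cycles` times, by which point the estimate is numerically converged on
#' the image sizes this pipeline works at (a 20 x 20 peak image converges
#' to within a gray level by 3-4 cycles).
#'
#' @param img numeric matrix, at least 2 x 2, values in \[0, 255\].
#' @param cycles number of repetitions of the step-halving schedule.
#' @return Matrix of the same shape spanning exactly \[0, 255\] for any
#'   non-constant input.
#' @export
retinex_enhance <- function(img, cycles = 4L) {
  img <- as.matrix(img)
  cycles <- as.integer(cycles)
  stopifnot(cycles >= 1L)
  m <- nrow(img); n <- ncol(img)
  if (m < 2L || n < 2L) stop("retinex needs an image of at least 2x2")
  if (any(!is.finite(img)) || any(img < 0))
    stop("image values must be finite and non-negative")
  rng <- range(img)
  if (rng[1L] == rng[2L]) return(array(0, dim(img)))
  d <- img * (255 / rng[2L]) + 1           # positive working copy, max 256
  P <- max(d)
  constant <- log10(P)
  L <- matrix(constant, m, n)
  log_d <- log10(d)
  # one ratio-product-reset-average update of pixels `to` against partners
  # `from` along rows (axis = 1) or columns (axis = 2)
  update <- function(L, to, from, axis) {
    est <- if (axis == 1L)
      L[from, , drop = FALSE] + log_d[to, , drop = FALSE] -
        log_d[from, , drop = FALSE]
    else
      L[, from, drop = FALSE] + log_d[, to, drop = FALSE] -
        log_d[, from, drop = FALSE]
    est <- pmin(constant, est)                       # reset
    if (axis == 1L)
      L[to, ] <- (est + L[to, , drop = FALSE]) / 2   # average
    else
      L[, to] <- (est + L[, to, drop = FALSE]) / 2
    L
  }
  for (cycle in seq_len(cycles)) {
    h <- max(1L, m %/% 2L)
    theta <- max(1L, n %/% 2L)
    repeat {
      if (h < m) {
        i <- seq_len(m - h)
        L <- update(L, i, i + h, 1L)     # partner below
        L <- update(L, i + h, i, 1L)     # partner above
      }
      if (theta < n) {
        j <- seq_len(n - theta)
        L <- update(L, j, j + theta, 2L) # partner right
        L <- update(L, j + theta, j, 2L) # partner left
      }
      if (h == 1L && theta == 1L) break
      h <- max(1L, h %/% 2L)
      theta <- max(1L, theta %/% 2L)
    }
  }
  normalize_gray(L)
}

# symmetric (edge-inclusive) padding of a matrix by r on every side
pad_symmetric <- function(img, r) {
  m <- nrow(img); n <- ncol(img)
  if (r >= m || r >= n)
    stop("padding radius must be smaller than both image sides")
  ri <- c(rev(seq_len(r)), seq_len(m), m + 1L - rev(seq_len(r)))
  ci <- c(rev(seq_len(r)), seq_len(n), n + 1L - rev(seq_len(r)))
  img[ri, ci, drop = FALSE]
}

#' Median filter
#'
#' Per-pixel median over a `window x window` neighborhood with symmetric
#' border extension.  Used right after Retinex enhancement, where isolated
#' bright "salt" pixels stand out on the small peak image.
#'
#' @param img numeric matrix.
#' @param window odd window side length, at least 3.
#' @return Filtered matrix of the same shape.
#' @export
median_filter <- function(img, window = 3L) {
  img <- as.matrix(img)
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("window must be an odd integer >= 3")
  r <- (window - 1L) %/% 2L
  m <- nrow(img); n <- ncol(img)
  pad <- pad_symmetric(img, r)
  slab <- array(NA_real_, c(m, n, window * window))
  k <- 0L
  for (di in 0:(window - 1L)) {
    for (dj in 0:(window - 1L)) {
      k <- k + 1L
      slab[, , k] <- pad[di + seq_len(m), dj + seq_len(n)]
    }
  }
  apply(slab, c(1L, 2L), median)
}
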