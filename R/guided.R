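# Box means with shrinking windows via an integral image: the mean over the
# intersection of the (2r+1)x(2r+1) window with the image, so borders are
# handled without padding.
box_mean <- function(x, r) {
  m <- nrow(x); n <- ncol(x)
  cs <- apply(x, 2L, cumsum)
  if (m == 1L) cs <- matrix(cs, 1L, n)
  cs2 <- t(apply(cs, 1L, cumsum))
  if (n == 1L) cs2 <- matrix(cs2, m, 1L)
  I <- matrix(0, m + 1L, n + 1L)
  I[-1L, -1L] <- cs2
  i1 <- pmax(seq_len(m) - r, 1L); i2 <- pmin(seq_len(m) + r, m)
  j1 <- pmax(seq_len(n) - r, 1L); j2 <- pmin(seq_len(n) + r, n)
  S <- I[i2 + 1L, j2 + 1L, drop = FALSE] -
       I[i1, j2 + 1L, drop = FALSE] -
       I[i2 + 1L, j1, drop = FALSE] +
       I[i1, j1, drop = FALSE]
  cnt <- outer(i2 - i1 + 1L, j2 - j1 + 1L)
  S / cnt
}

#' Self-guided edge-preserving filter
#'
#' Assumes the output is locally an affine function of the input within each
#' sliding window: with window mean `mu_k` and variance `sigma2_k`, the
#' window coefficients are `a_k = sigma2_k / (sigma2_k + eps)` and
#' `b_k = (1 - a_k) * mu_k`; the output at a pixel averages the
#' coefficients of every window covering it.  Large `eps` smooths more; in
#' flat regions (`sigma2 << eps`) the filter approaches a box blur, at
#' strong edges (`sigma2 >> eps`) it passes the input through.  Windows
#' shrink at the borders (statistics over the valid pixels only).
#'
#' @param p numeric matrix (any scale — the math is scale-consistent), or a
#'   3-channel array, filtered channel by channel.
#' @param r window radius in pixels (window side `2r + 1`); alternatively a
#'   [adaptive_params()] object, in which case `p` is interpreted on the
#'   \[0, 255\] scale, filtered on \[0, 1\] with the object's converted
#'   `eps01`, and rescaled back.
#' @param eps regularization, same squared units as `p` (ignored when `r`
#'   is a parameter object).
#' @return Filtered matrix/array of the same shape.
#' @export
guided_filter <- function(p, r, eps = NULL) {
  if (inherits(r, "guided_params")) {
    params <- r
    if (length(dim(p)) == 3L) {
      out <- p
      for (ch in seq_len(dim(p)[3L]))
        out[, , ch] <- 255 * guided_filter_core(p[, , ch] / 255,
                                                params$r, params$eps01)
      return(out)
    }
    return(255 * guided_filter_core(as.matrix(p) / 255,
                                    params$r, params$eps01))
  }
  if (is.null(eps)) stop("eps must be supplied with a numeric radius")
  if (length(dim(p)) == 3L) {
    out <- p
    for (ch in seq_len(dim(p)[3L]))
      out[, , ch] <- guided_filter_core(p[, , ch], r, eps)
    return(out)
  }
  guided_filter_core(as.matrix(p), r, eps)
}

guided_filter_core <- function(p, r, eps) {
  r <- as.integer(r)
  stopifnot(r >= 1L, eps > 0)
  m <- nrow(p); n <- ncol(p)
  if (m < 2L * r + 1L || n < 2L * r + 1L)
    stop("image smaller than the filter window")
  mu <- box_mean(p, r)
  mu2 <- box_mean(p * p, r)
  sigma2 <- pmax(mu2 - mu * mu, 0)
  a <- sigma2 / (sigma2 + eps)
  b <- (1 - a) * mu
  box_mean(a, r) * p + box_mean(b, r)
}
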