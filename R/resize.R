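# Separable image resampling.
#
# Both bilinear and bicubic resizing are expressed as a pair of row/column
# weight matrices so that resize(img) = Wr %*% img %*% t(Wc).  Sampling uses
# the pixel-center convention: output center i maps to input coordinate
# (i - 0.5) * n_in/n_out + 0.5, with edge clamping.  Kernel weights sum to 1
# per row, so constants are preserved exactly.

cubic_kernel <- function(x, a = -0.5) {
  x <- abs(x)
  ifelse(x <= 1, (a + 2) * x^3 - (a + 3) * x^2 + 1,
         ifelse(x < 2, a * x^3 - 5 * a * x^2 + 8 * a * x - 4 * a, 0))
}

resample_weights <- function(n_in, n_out, method = c("bilinear", "bicubic")) {
  method <- match.arg(method)
  scale <- n_in / n_out
  src <- (seq_len(n_out) - 0.5) * scale + 0.5
  W <- matrix(0, n_out, n_in)
  taps <- if (method == "bilinear") 0:1 else -1:2
  base <- floor(src)
  frac <- src - base
  for (t in taps) {
    idx <- base + t
    w <- if (method == "bilinear") {
      if (t == 0) 1 - frac else frac
    } else {
      cubic_kernel(t - frac)
    }
    idx <- pmin(pmax(idx, 1), n_in)        # clamp: edge replication
    W[cbind(seq_len(n_out), idx)] <- W[cbind(seq_len(n_out), idx)] + w
  }
  W / rowSums(W)
}

#' Resize a grayscale raster
#'
#' Separable bilinear or bicubic (Catmull-Rom, a = -0.5) resampling with
#' pixel-center alignment and edge clamping.
#'
#' @param img numeric matrix.
#' @param out_h,out_w output dimensions (positive integers).
#' @param method `"bilinear"` or `"bicubic"`.
#' @return `out_h x out_w` numeric matrix.
#' @export
resize_gray <- function(img, out_h, out_w, method = c("bilinear", "bicubic")) {
  method <- match.arg(method)
  img <- as.matrix(img)
  out_h <- as.integer(out_h); out_w <- as.integer(out_w)
  stopifnot(out_h >= 1L, out_w >= 1L)
  Wr <- resample_weights(nrow(img), out_h, method)
  Wc <- resample_weights(ncol(img), out_w, method)
  Wr %*% img %*% t(Wc)
}

#' Upscale a small raster to a minimum working size
#'
#' Point-scan grids can be as small as 10 x 10; images below `min_side` on
#' both sides are bilinearly upscaled (aspect preserved, round half up) so
#' the smaller side equals `min_side`.  Larger images pass through.
#'
#' @param img numeric matrix.
#' @param min_side minimum working side length in pixels (default 20).
#' @param force upscale when *either* side is below `min_side` instead of
#'   requiring both (default `FALSE`, the literal size rule).
#' @return Numeric matrix, possibly upscaled.
#' @export
resize_to_min <- function(img, min_side = 20L, force = FALSE) {
  img <- as.matrix(img)
  min_side <- as.integer(min_side)
  stopifnot(min_side >= 1L)
  a <- nrow(img); b <- ncol(img)
  small <- if (force) (a < min_side || b < min_side)
           else (a < min_side && b < min_side)
  if (!small) return(img)
  scale <- min_side / min(a, b)
  round_half_up <- function(x) floor(x + 0.5)
  resize_gray(img, round_half_up(a * scale), round_half_up(b * scale),
              "bilinear")
}
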