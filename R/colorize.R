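#' Jet pseudo-color mapping
#'
#' Maps a grayscale image onto the classic blue-cyan-green-yellow-red ramp
#' using the standard piecewise-linear formulation: with `v = gray/255`,
#' `R = clip(min(4v - 1.5, -4v + 4.5))`, `G = clip(min(4v - 0.5,
#' -4v + 3.5))`, `B = clip(min(4v + 0.5, -4v + 2.5))`, each channel scaled
#' by 255 and rounded half-up.  Gray 0 maps to (0, 0, 128) and gray 255 to
#' (128, 0, 0), the documented colormap endpoints.
#'
#' @param img numeric matrix in \[0, 255\].
#' @return Integer array `nrow x ncol x 3` (R, G, B in \[0, 255\]).
#' @export
jet_colorize <- function(img) {
  img <- as.matrix(img)
  if (any(!is.finite(img))) stop("image values must be finite")
  v <- pmin(pmax(img / 255, 0), 1)
  clip01 <- function(x) pmin(pmax(x, 0), 1)
  r <- clip01(pmin(4 * v - 1.5, -4 * v + 4.5))
  g <- clip01(pmin(4 * v - 0.5, -4 * v + 3.5))
  b <- clip01(pmin(4 * v + 0.5, -4 * v + 2.5))
  round_half_up <- function(x) as.integer(floor(x + 0.5))
  out <- array(0L, c(nrow(img), ncol(img), 3L))
  out[, , 1L] <- round_half_up(255 * r)
  out[, , 2L] <- round_half_up(255 * g)
  out[, , 3L] <- round_half_up(255 * b)
  out
}

#' 256-entry Jet lookup table
#'
#' The colormap evaluated at every integer gray level; identical to
#' applying [jet_colorize()] level by level.
#'
#' @return Integer 256 x 3 matrix with columns R, G, B.
#' @export
jet_lut <- function() {
  m <- jet_colorize(matrix(0:255, ncol = 1L))
  lut <- cbind(R = m[, 1L, 1L], G = m[, 1L, 2L], B = m[, 1L, 3L])
  rownames(lut) <- 0:255
  lut
}
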