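#' Peak signal-to-noise ratio between two rasters
#'
#' `MSE` is the mean squared pixel difference (color images average over
#' the three channels as well); `PSNR = 20 * log10(255 / sqrt(MSE))` in dB.
#' Identical images have `MSE = 0` and PSNR `Inf`.
#'
#' @param imgI,imgK numeric matrices or `h x w x 3` arrays of identical
#'   shape, gray values on the 0-255 scale.
#' @return List with `mse` and `psnr_db`.
#' @export
psnr <- function(imgI, imgK) {
  if (!identical(dim(imgI), dim(imgK)))
    stop("images must have identical dimensions")
  mse <- mean((as.numeric(imgI) - as.numeric(imgK))^2)
  list(mse = mse,
       psnr_db = if (mse == 0) Inf else 20 * log10(255 / sqrt(mse)))
}

# quantize gray values to integer levels 0..255
quantize255 <- function(x) pmin(pmax(as.integer(floor(x + 0.5)), 0L), 255L)

#' Shannon entropy of a grayscale image
#'
#' Histogram over the 256 integer gray levels, `p_i = f(i) / (a*b)`,
#' entropy `-sum p_i log2 p_i` in bits (`0 log 0 := 0`).
#'
#' @param img numeric matrix (or one color channel), 0-255 scale.
#' @return Entropy in bits.
#' @export
entropy_gray <- function(img) {
  f <- tabulate(quantize255(as.numeric(img)) + 1L, nbins = 256L)
  p <- f / sum(f)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Shannon entropy of a color image
#'
#' Joint histogram over the observed (R, G, B) triples, normalized by the
#' pixel count so the probabilities sum to 1; entropy in bits.
#'
#' @param rgb integer array `h x w x 3`, values 0-255.
#' @return Entropy in bits.
#' @export
entropy_color <- function(rgb) {
  stopifnot(length(dim(rgb)) == 3L, dim(rgb)[3L] == 3L)
  r <- quantize255(as.numeric(rgb[, , 1L]))
  g <- quantize255(as.numeric(rgb[, , 2L]))
  b <- quantize255(as.numeric(rgb[, , 3L]))
  code <- (as.numeric(r) * 256 + g) * 256 + b
  f <- table(code)
  p <- as.numeric(f) / length(code)
  -sum(p * log2(p))
}

#' Per-channel entropies of a color image
#'
#' @param rgb integer array `h x w x 3`.
#' @return Named numeric vector `c(R =, G =, B =)` in bits.
#' @export
entropy_channels <- function(rgb) {
  stopifnot(length(dim(rgb)) == 3L, dim(rgb)[3L] == 3L)
  c(R = entropy_gray(rgb[, , 1L]),
    G = entropy_gray(rgb[, , 2L]),
    B = entropy_gray(rgb[, , 3L]))
}

# CIELAB (L*, C*, h) histogram of an RGB image; fixed binning:
# L* 10 bins over [0,100], C* 10 bins over [0,150], h 36 bins over [0,360).
lab_histogram <- function(rgb, n_l = 10L, n_c = 10L, n_h = 36L) {
  stopifnot(length(dim(rgb)) == 3L, dim(rgb)[3L] == 3L)
  px <- cbind(as.numeric(rgb[, , 1L]),
              as.numeric(rgb[, , 2L]),
              as.numeric(rgb[, , 3L])) / 255
  lab <- grDevices::convertColor(px, from = "sRGB", to = "Lab")
  L <- lab[, 1L]
  C <- sqrt(lab[, 2L]^2 + lab[, 3L]^2)
  hdeg <- (atan2(lab[, 3L], lab[, 2L]) * 180 / pi) %% 360
  li <- pmin(pmax(floor(L / (100 / n_l)), 0), n_l - 1L)
  ci <- pmin(pmax(floor(C / (150 / n_c)), 0), n_c - 1L)
  hi <- floor(hdeg / (360 / n_h)) %% n_h
  idx <- (li * n_c + ci) * n_h + hi + 1L
  tabulate(idx, nbins = n_l * n_c * n_h)
}

#' CIELAB histogram KL-divergence between two images
#'
#' Both images are converted to CIELAB (D65/2 degrees) and summarized as
#' (L*, C*, h) histograms on a fixed 10 x 10 x 36 grid; after Laplace
#' smoothing `alpha` and renormalization the statistic is
#' `|sum p log10(p/q)|`.  Near-zero values mean the images have closely
#' matching color-structure distributions; the measure is used as a
#' no-reference sharpness/clarity comparison and is asymmetric in (p, q)
#' apart from the absolute value.  The images may have different sizes —
#' distributions, not pixels, are compared.
#'
#' @param imgP,imgQ integer arrays `h x w x 3` (0-255).
#' @param alpha Laplace smoothing added to every bin (default 1e-6).
#' @return Non-negative divergence (log base 10).
#' @export
kl_sharpness <- function(imgP, imgQ, alpha = 1e-6) {
  hp <- lab_histogram(imgP)
  hq <- lab_histogram(imgQ)
  p <- (hp / sum(hp)) + alpha
  q <- (hq / sum(hq)) + alpha
  p <- p / sum(p)
  q <- q / sum(q)
  abs(sum(p * log10(p / q)))
}

#' Quality report for a pseudo-color result
#'
#' Bundles the package's evaluation metrics for a final color image:
#' color and per-channel entropies, plus — when a pre-filter reference is
#' given — MSE/PSNR of the smoothed gray against the unsmoothed gray and
#' the CIELAB KL-divergence of the color result against the unsmoothed
#' colorization.
#'
#' @param rgb final color image (`h x w x 3`).
#' @param gray final grayscale image, optional.
#' @param gray_ref pre-filter grayscale reference, optional.
#' @param rgb_ref pre-filter color reference, optional.
#' @return An object of class `metric_report` (a list).
#' @export
metric_report <- function(rgb, gray = NULL, gray_ref = NULL, rgb_ref = NULL) {
  rep <- list(entropy_bits = entropy_color(rgb),
              channel_entropies = entropy_channels(rgb),
              gray_entropy_bits = if (is.null(gray)) NA_real_
                                  else entropy_gray(gray))
  if (!is.null(gray) && !is.null(gray_ref)) {
    ps <- psnr(gray_ref, gray)
    rep$mse <- ps$mse
    rep$psnr_db <- ps$psnr_db
  } else {
    rep$mse <- NA_real_; rep$psnr_db <- NA_real_
  }
  rep$kl_divergence <- if (is.null(rgb_ref)) NA_real_
                       else kl_sharpness(rgb, rgb_ref)
  structure(rep, class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("metric_report:\n")
  cat(sprintf("  color entropy: %.4f bits (R %.4f, G %.4f, B %.4f)\n",
              x$entropy_bits, x$channel_entropies[["R"]],
              x$channel_entropies[["G"]], x$channel_entropies[["B"]]))
  if (is.finite(x$psnr_db))
    cat(sprintf("  filter MSE %.4f, PSNR %.4f dB\n", x$mse, x$psnr_db))
  if (!is.na(x$kl_divergence))
    cat(sprintf("  CIELAB KL vs unfiltered: %.6f\n", x$kl_divergence))
  invisible(x)
}
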