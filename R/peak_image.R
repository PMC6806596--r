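#' Peak-intensity grayscale image from a spectral scan
#'
#' Each scan point becomes one pixel.  The pixel value is the maximum
#' in-band intensity at that point (`n_sym = 0`), or the mean of the peak
#' sample and its `n_sym` symmetric neighbors (`n_sym/2` channels per side,
#' clipped at the band edges).  Averaging neighbors raises contrast but also
#' amplifies salt-like noise, so the default takes the bare maximum.
#' Pixels are laid out row-major: point 1 is the top-left pixel.
#'
#' @param scan a [spectral_scan()] with `repeats == 1` (see
#'   [average_repeats()]).
#' @param band a [band_window()] restricting the spectral search.
#' @param n_sym number of symmetric neighbors to average: 0, 4, 8 or 12.
#' @return A numeric `grid_rows x grid_cols` matrix of raw (un-normalized)
#'   intensities.
#' @seealso [normalize_gray()] to map onto \[0, 255\].
#' @export
extract_peak_image <- function(scan, band, n_sym = 0L) {
  stopifnot(inherits(scan, "spectral_scan"))
  if (scan$repeats != 1L)
    stop("scan has repeats > 1; call average_repeats() first")
  n_sym <- as.integer(n_sym)
  if (!(n_sym %in% c(0L, 4L, 8L, 12L)))
    stop("n_sym must be one of 0, 4, 8, 12")
  idx <- band_indices(scan$wavenumbers, band)
  sub <- scan$intensities[, idx, drop = FALSE]
  # ties: first (lowest-wavenumber) maximal channel wins
  peak_at <- max.col(sub, ties.method = "first")
  if (n_sym == 0L) {
    vals <- sub[cbind(seq_len(nrow(sub)), peak_at)]
  } else {
    half <- n_sym %/% 2L
    nb <- ncol(sub)
    vals <- vapply(seq_len(nrow(sub)), function(r) {
      lo <- max(1L, peak_at[r] - half)
      hi <- min(nb, peak_at[r] + half)
      mean(sub[r, lo:hi])
    }, numeric(1L))
  }
  matrix(vals, nrow = scan$grid_rows, ncol = scan$grid_cols, byrow = TRUE)
}

#' Normalize a raw intensity raster to \[0, 255\]
#'
#' Affine stretch sending the minimum to 0 and the maximum to 255.  A
#' constant raster (zero dynamic range) maps to all zeros.
#'
#' @param img numeric matrix of finite values.
#' @return Matrix of the same shape with values in \[0, 255\].
#' @export
normalize_gray <- function(img) {
  img <- as.matrix(img)
  if (any(!is.finite(img))) stop("image values must be finite")
  rng <- range(img)
  if (rng[1L] == rng[2L]) return(array(0, dim(img)))
  (img - rng[1L]) / (rng[2L] - rng[1L]) * 255
}

#' Per-point band variance map
#'
#' The population variance of each point's in-band intensities.  Points
#' whose spectra change sharply across the band (large variance) mark the
#' cell body; thresholding the map (default 1000 intensity^2) approximates
#' the cell boundary and the count of super-threshold points feeds the
#' adaptive guided-filter model.
#'
#' @param scan a [spectral_scan()] with `repeats == 1`.
#' @param band a [band_window()] with at least 2 channels inside.
#' @param threshold variance threshold for the `n_above` count.
#' @return An object of class `variance_map`: list with `values`
#'   (`grid_rows x grid_cols` matrix), `threshold`, `n_above`.
#' @export
band_variance_map <- function(scan, band, threshold = 1000) {
  stopifnot(inherits(scan, "spectral_scan"))
  if (scan$repeats != 1L)
    stop("scan has repeats > 1; call average_repeats() first")
  idx <- band_indices(scan$wavenumbers, band)
  if (length(idx) < 2L)
    stop("band must contain at least 2 channels for a variance")
  sub <- scan$intensities[, idx, drop = FALSE]
  mu <- rowMeans(sub)
  v <- rowMeans(sub * sub) - mu * mu   # population variance, divisor |band|
  v <- pmax(v, 0)                       # guard tiny negative rounding
  vm <- matrix(v, nrow = scan$grid_rows, ncol = scan$grid_cols, byrow = TRUE)
  structure(list(values = vm, threshold = threshold,
                 n_above = sum(vm > threshold)),
            class = "variance_map")
}

#' @export
print.variance_map <- function(x, ...) {
  cat(sprintf("variance_map: %dx%d, threshold %g, %d point(s) above\n",
              nrow(x$values), ncol(x$values), x$threshold, x$n_above))
  invisible(x)
}

#' Summarize a variance map to the scalar fed to the adaptive filter model
#'
#' The adaptive parameter model consumes a single band-variance number while
#' the map is per-point; the summary mode (mean by default) is the bridge.
#'
#' @param vm a [band_variance_map()] result.
#' @param mode one of `"mean"`, `"median"`, `"max"`.
#' @return A scalar variance.
#' @export
summarize_sigma2 <- function(vm, mode = c("mean", "median", "max")) {
  stopifnot(inherits(vm, "variance_map"))
  mode <- match.arg(mode)
  v <- vm$values
  if (!length(v)) stop("empty variance map")
  switch(mode, mean = mean(v), median = median(v), max = max(v))
}
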