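#' Synthetic Raman scene specification
#'
#' Describes a point-scan acquisition of elliptical "cells" on a clean
#' substrate, emulating the reference instrument setup: a 20 x 20 grid of
#' points, 1024 spectral channels over 155-3926 cm^-1, each point scanned
#' twice.  Inside a cell the CH-stretch peak (2930 cm^-1) is strong; the
#' substrate carries the same broad fluorescence baseline with a weak
#' residual peak.  Noise: additive Gaussian, signal-proportional
#' (shot-like, Gaussian approximation) and occasional large positive
#' single-channel spikes ("salt").
#'
#' @param grid_rows,grid_cols scan grid size.
#' @param n_channels spectral channels.
#' @param wn_lo,wn_hi wavenumber range (cm^-1).
#' @param cells list of ellipses, each `list(row =, col =, a =, b =)`
#'   (center and semi-axes in grid units).
#' @param peak_center,peak_width Gaussian peak position and width (cm^-1).
#' @param peak_amp_inside,peak_amp_outside peak amplitude inside / outside
#'   a cell (intensity counts).
#' @param baseline_scale amplitude of the broad fluorescence polynomial.
#' @param gauss_sigma additive Gaussian noise s.d.
#' @param shot_scale variance-per-count of the shot-like noise.
#' @param salt_prob probability of one salt spike per (point, repeat).
#' @param salt_amp spike amplitude.
#' @param repeats measurements per point.
#' @param seed RNG seed; the scan is fully determined by it.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_rows = 20L, grid_cols = 20L,
                         n_channels = 1024L, wn_lo = 155, wn_hi = 3926,
                         cells = list(
                           list(row = 8, col = 8, a = 4, b = 2.5),
                           list(row = 14, col = 13.5, a = 3, b = 2)),
                         peak_center = 2930, peak_width = 30,
                         peak_amp_inside = 2000, peak_amp_outside = 200,
                         baseline_scale = 300,
                         gauss_sigma = 30, shot_scale = 0.5,
                         salt_prob = 0.02, salt_amp = 10000,
                         repeats = 2L, seed = 1L) {
  spec <- list(grid_rows = as.integer(grid_rows),
               grid_cols = as.integer(grid_cols),
               n_channels = as.integer(n_channels),
               wn_lo = wn_lo, wn_hi = wn_hi, cells = cells,
               peak_center = peak_center, peak_width = peak_width,
               peak_amp_inside = peak_amp_inside,
               peak_amp_outside = peak_amp_outside,
               baseline_scale = baseline_scale,
               gauss_sigma = gauss_sigma, shot_scale = shot_scale,
               salt_prob = salt_prob, salt_amp = salt_amp,
               repeats = as.integer(repeats), seed = as.integer(seed))
  with(spec, {
    if (grid_rows < 1L || grid_cols < 1L || n_channels < 2L || repeats < 1L)
      stop("invalid grid/channel/repeat counts")
    if (wn_lo >= wn_hi) stop("wn_lo must be below wn_hi")
    if (salt_prob < 0 || salt_prob > 1) stop("salt_prob must be in [0, 1]")
    if (peak_amp_inside < 0 || peak_amp_outside < 0 || baseline_scale < 0 ||
        gauss_sigma < 0 || shot_scale < 0 || salt_amp < 0 ||
        peak_width <= 0)
      stop("amplitudes and noise scales must be non-negative")
    for (cl in cells) {
      if (cl$a <= 0 || cl$b <= 0) stop("ellipse semi-axes must be positive")
      if (cl$row - cl$a < 0.5 || cl$row + cl$a > grid_rows + 0.5 ||
          cl$col - cl$b < 0.5 || cl$col + cl$b > grid_cols + 0.5)
        stop("ellipse extends outside the grid")
    }
  })
  structure(spec, class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "phantom_spec: %dx%d grid, %d channels %g-%g cm^-1, %d cell(s), %d repeat(s), seed %d\n",
    x$grid_rows, x$grid_cols, x$n_channels, x$wn_lo, x$wn_hi,
    length(x$cells), x$repeats, x$seed))
  invisible(x)
}

#' Generate a synthetic Raman scan with ground truth
#'
#' Per point and repeat: spectrum = fluorescence baseline (a fixed
#' low-order polynomial scaled by `baseline_scale`) + a Gaussian peak at
#' `peak_center` whose amplitude depends on cell membership + Gaussian
#' noise + shot-like noise (Gaussian with variance `shot_scale * signal`)
#' + an occasional salt spike.  Intensities are clamped at zero.
#'
#' @param spec a [phantom_spec()].
#' @return List with `scan` (a [spectral_scan()]) and `mask`
#'   (`grid_rows x grid_cols` 0/1 matrix of cell membership).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  wn <- seq(spec$wn_lo, spec$wn_hi, length.out = spec$n_channels)
  t <- (wn - spec$wn_lo) / (spec$wn_hi - spec$wn_lo)
  baseline <- spec$baseline_scale * (1.2 + 1.8 * t - 2.4 * t^2 + 0.9 * t^3)
  peak_shape <- exp(-(wn - spec$peak_center)^2 / (2 * spec$peak_width^2))

  mask <- matrix(0L, spec$grid_rows, spec$grid_cols)
  for (cl in spec$cells) {
    for (i in seq_len(spec$grid_rows))
      for (j in seq_len(spec$grid_cols))
        if (((i - cl$row) / cl$a)^2 + ((j - cl$col) / cl$b)^2 <= 1)
          mask[i, j] <- 1L
  }

  n_pts <- spec$grid_rows * spec$grid_cols
  inten <- matrix(0, n_pts * spec$repeats, spec$n_channels)
  # row-major point order to match the scan layout
  inside <- as.vector(t(mask)) == 1L
  row_i <- 0L
  for (p in seq_len(n_pts)) {
    amp <- if (inside[p]) spec$peak_amp_inside else spec$peak_amp_outside
    signal <- baseline + amp * peak_shape
    for (rep_k in seq_len(spec$repeats)) {
      row_i <- row_i + 1L
      y <- signal
      if (spec$gauss_sigma > 0)
        y <- y + rnorm(spec$n_channels, 0, spec$gauss_sigma)
      if (spec$shot_scale > 0)
        y <- y + rnorm(spec$n_channels) * sqrt(spec$shot_scale * pmax(signal, 0))
      if (spec$salt_prob > 0 && runif(1) < spec$salt_prob) {
        ch <- sample.int(spec$n_channels, 1L)
        y[ch] <- y[ch] + spec$salt_amp
      }
      inten[row_i, ] <- pmax(y, 0)
    }
  }
  list(scan = spectral_scan(wn, inten, spec$grid_rows, spec$grid_cols,
                            spec$repeats),
       mask = mask)
}

#' Dice overlap between two binary masks
#'
#' `2|A n B| / (|A| + |B|)`; 1 when both masks are empty.
#'
#' @param a,b logical or 0/1 matrices of identical shape.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice_overlap <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("masks must have identical shapes")
  a <- a > 0; b <- b > 0
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
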