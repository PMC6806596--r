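#' Pipeline configuration
#'
#' Bundles every tunable of the scan-to-pseudo-color pipeline with the
#' reference defaults: CH-stretch band 2750-3050 cm^-1, bare peak maxima
#' (`n_sym = 0`), 3 x 3 median window, minimum working size 20 px, target
#' size 320 px with x2 steps, variance threshold 1000, built-in adaptive
#' coefficients, Jet colormap.
#'
#' @param band a [band_window()]; `NULL` selects the scan's full axis at
#'   run time.
#' @param n_sym symmetric neighbors averaged around the peak (0/4/8/12).
#' @param median_window odd median-filter window.
#' @param min_size minimum working image side before median filtering.
#' @param force_min_resize upscale when either side (not both) is small.
#' @param target_size minimum side of the super-resolved image.
#' @param sr_scale upscale factor per super-resolution iteration.
#' @param weights an [srcnn_weights()], `NULL` for the deterministic
#'   default recipe, or `NA` to skip the network (bicubic-only ablation).
#' @param coefficients an [adaptive_coefficients()] object.
#' @param var_threshold band-variance threshold for `N2`.
#' @param sigma2_mode summary mode for the variance map
#'   (`"mean"`/`"median"`/`"max"`).
#' @param filter_rgb apply the guided filter per color channel after
#'   colorization instead of on the gray image before it.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(band = band_window(2750, 3050), n_sym = 0L,
                            median_window = 3L, min_size = 20L,
                            force_min_resize = FALSE,
                            target_size = 320L, sr_scale = 2L,
                            weights = NULL,
                            coefficients = builtin_adaptive_coefficients(),
                            var_threshold = 1000,
                            sigma2_mode = "mean",
                            filter_rgb = FALSE) {
  if (!is.null(band)) stopifnot(inherits(band, "band_window"))
  stopifnot(inherits(coefficients, "adaptive_coefficients"))
  structure(list(band = band, n_sym = as.integer(n_sym),
                 median_window = as.integer(median_window),
                 min_size = as.integer(min_size),
                 force_min_resize = isTRUE(force_min_resize),
                 target_size = as.integer(target_size),
                 sr_scale = as.integer(sr_scale),
                 weights = weights, coefficients = coefficients,
                 var_threshold = var_threshold,
                 sigma2_mode = sigma2_mode,
                 filter_rgb = isTRUE(filter_rgb)),
            class = "pipeline_config")
}

#' Run the scan-to-pseudo-color pipeline
#'
#' Executes the full chain: average repeats, extract the band-limited peak
#' image, normalize, Retinex-enhance, upscale to the minimum working size
#' if needed, median-filter, super-resolve to the target size, derive the
#' adaptive guided-filter parameters from the scan statistics, smooth, and
#' colorize with the Jet map.  Metrics compare the smoothed result with
#' the unsmoothed one (there is no external reference image).
#'
#' @param scan a [spectral_scan()].
#' @param cfg a [pipeline_config()].
#' @param debug_dir when non-`NULL`, every intermediate raster is written
#'   there as PGM/PPM.
#' @return An object of class `pipeline_result`: list with `rgb` (final
#'   color array), `gray` (final grayscale), `stages` (named list of
#'   intermediates), `params` (the [adaptive_params()] used), `variance`
#'   (the [band_variance_map()]), `metrics` (a [metric_report()]).
#' @export
run_pipeline <- function(scan, cfg = pipeline_config(), debug_dir = NULL) {
  stopifnot(inherits(scan, "spectral_scan"),
            inherits(cfg, "pipeline_config"))
  band <- if (is.null(cfg$band)) full_band(scan) else cfg$band
  weights <- cfg$weights
  if (is.null(weights)) weights <- default_srcnn_weights()
  else if (!inherits(weights, "srcnn_weights")) weights <- NULL  # ablation

  st <- list()
  averaged <- average_repeats(scan)
  st$peak_raw <- extract_peak_image(averaged, band, cfg$n_sym)
  st$normalized <- normalize_gray(st$peak_raw)
  st$retinex <- retinex_enhance(st$normalized)
  st$resized <- resize_to_min(st$retinex, cfg$min_size,
                              force = cfg$force_min_resize)
  st$median <- median_filter(st$resized, cfg$median_window)
  st$superres <- superresolve(st$median, weights,
                              target_min = cfg$target_size,
                              scale = cfg$sr_scale)

  vm <- band_variance_map(averaged, band, cfg$var_threshold)
  sigma2 <- summarize_sigma2(vm, cfg$sigma2_mode)
  params <- adaptive_params(N1 = averaged$grid_rows * averaged$grid_cols,
                            N2 = vm$n_above, sigma2 = sigma2,
                            coef = cfg$coefficients)

  rgb_unfiltered <- jet_colorize(st$superres)
  if (cfg$filter_rgb) {
    st$filtered <- st$superres
    rgb <- guided_filter(rgb_unfiltered, params)
    rgb <- array(as.integer(floor(pmin(pmax(rgb, 0), 255) + 0.5)), dim(rgb))
  } else {
    st$filtered <- guided_filter(st$superres, params)
    rgb <- jet_colorize(st$filtered)
  }

  metrics <- metric_report(rgb, gray = st$filtered, gray_ref = st$superres,
                           rgb_ref = rgb_unfiltered)

  if (!is.null(debug_dir)) {
    dir.create(debug_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(st))
      write_pgm(st[[nm]], file.path(debug_dir, paste0(nm, ".pgm")))
    write_ppm(rgb, file.path(debug_dir, "final.ppm"))
  }

  structure(list(rgb = rgb, gray = st$filtered, stages = st,
                 params = params, variance = vm, metrics = metrics),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline_result: %dx%d pseudo-color image\n",
              dim(x$rgb)[1L], dim(x$rgb)[2L]))
  print(x$params)
  print(x$metrics)
  invisible(x)
}

#' Warm-color cell mask of a pipeline result
#'
#' Pixels whose underlying gray value exceeds `v * 255` map to the warm
#' (yellow-to-red) end of the Jet ramp and are read as "cell".
#'
#' @param result a [run_pipeline()] result.
#' @param v gray threshold on the \[0, 1\] scale (default 0.6).
#' @return Logical matrix of the final image size.
#' @export
warm_mask <- function(result, v = 0.6) {
  stopifnot(inherits(result, "pipeline_result"))
  result$gray > v * 255
}

#' Nearest-neighbor upscale of a grid mask to an image size
#'
#' @param mask 0/1 matrix (scan-grid resolution).
#' @param out_h,out_w target size in pixels.
#' @return Logical `out_h x out_w` matrix.
#' @export
upsample_mask <- function(mask, out_h, out_w) {
  m <- nrow(mask); n <- ncol(mask)
  ri <- pmin(pmax(ceiling((seq_len(out_h) - 0.5) * m / out_h), 1L), m)
  ci <- pmin(pmax(ceiling((seq_len(out_w) - 0.5) * n / out_w), 1L), n)
  mask[ri, ci, drop = FALSE] > 0
}
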