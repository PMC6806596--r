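#' Point-scan Raman spectral data
#'
#' A `spectral_scan` holds the spectra of a rectangular grid of scan points.
#' Each point may have been measured several times ("repeats"); repeats are
#' stored as consecutive rows.  Points are ordered row-major from the
#' top-left corner of the grid.
#'
#' @param wavenumbers numeric vector of spectral positions (cm^-1), strictly
#'   increasing.
#' @param intensities numeric matrix of non-negative intensities; one row per
#'   (point, repeat), columns aligned with `wavenumbers`.
#' @param grid_rows,grid_cols grid dimensions (positive integers).
#' @param repeats number of consecutive measurements per point.
#'
#' @return An object of class `spectral_scan`: a list with fields
#'   `wavenumbers`, `intensities`, `grid_rows`, `grid_cols`, `repeats`,
#'   `scan_order` (always `"row_major"`).
#' @export
spectral_scan <- function(wavenumbers, intensities, grid_rows, grid_cols,
                          repeats = 1L) {
  wavenumbers <- as.numeric(wavenumbers)
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  grid_rows <- as.integer(grid_rows)
  grid_cols <- as.integer(grid_cols)
  repeats <- as.integer(repeats)
  if (grid_rows < 1L || grid_cols < 1L || repeats < 1L)
    stop("grid_rows, grid_cols and repeats must be positive integers")
  if (length(wavenumbers) < 1L)
    stop("wavenumber axis is empty")
  if (any(!is.finite(wavenumbers)) || any(diff(wavenumbers) <= 0))
    stop("wavenumbers must be finite and strictly increasing")
  if (ncol(intensities) != length(wavenumbers))
    stop(sprintf("intensity columns (%d) do not match wavenumber axis (%d)",
                 ncol(intensities), length(wavenumbers)))
  expected <- grid_rows * grid_cols * repeats
  if (nrow(intensities) != expected)
    stop(sprintf(
      "geometry error: %d spectra but grid %dx%d with %d repeat(s) needs %d",
      nrow(intensities), grid_rows, grid_cols, repeats, expected))
  if (any(!is.finite(intensities)))
    stop("intensities must be finite")
  if (any(intensities < 0))
    stop("intensities must be non-negative")
  structure(
    list(wavenumbers = wavenumbers, intensities = intensities,
         grid_rows = grid_rows, grid_cols = grid_cols, repeats = repeats,
         scan_order = "row_major"),
    class = "spectral_scan")
}

#' @export
print.spectral_scan <- function(x, ...) {
  cat(sprintf(
    "spectral_scan: %dx%d grid, %d repeat(s), %d channels (%.1f-%.1f cm^-1)\n",
    x$grid_rows, x$grid_cols, x$repeats, length(x$wavenumbers),
    min(x$wavenumbers), max(x$wavenumbers)))
  invisible(x)
}

#' Read a point-scan spectral file
#'
#' The file dialect is plain text, tab- or comma-separated: row 1 is the
#' wavenumber axis, each following row one spectrum.  Repeated measurements
#' of a point are consecutive rows.  Grid geometry is not embedded in the
#' file and must be supplied.
#'
#' @param path file to read.
#' @param grid_rows,grid_cols,repeats declared geometry; the row count of the
#'   file must equal `grid_rows * grid_cols * repeats + 1`.
#' @param sep field separator; `NULL` (default) auto-detects tab vs comma
#'   from the header line.
#' @return A validated [spectral_scan()].
#' @export
read_scan <- function(path, grid_rows, grid_cols, repeats = 1L, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("format error: need a header row and spectra")
  if (is.null(sep))
    sep <- if (grepl("\t", lines[[1L]])) "\t" else ","
  fields <- strsplit(lines, sep, fixed = TRUE)
  nfield <- lengths(fields)
  if (any(nfield != nfield[[1L]]))
    stop(sprintf("format error: ragged rows (row %d has %d fields, expected %d)",
                 which(nfield != nfield[[1L]])[1L],
                 nfield[which(nfield != nfield[[1L]])[1L]], nfield[[1L]]))
  vals <- suppressWarnings(lapply(fields, as.numeric))
  bad <- which(vapply(vals, function(v) any(is.na(v)), logical(1L)))
  if (length(bad))
    stop(sprintf("parse error: non-numeric cell in row %d", bad[[1L]]))
  wn <- vals[[1L]]
  mat <- do.call(rbind, vals[-1L])
  spectral_scan(wn, mat, grid_rows, grid_cols, repeats)
}

#' Write a point-scan spectral file
#'
#' Inverse of [read_scan()]: tab-separated, wavenumber header first.  Values
#' are written with 17 significant digits so a round trip is numerically
#' exact.
#'
#' @param scan a [spectral_scan()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_scan <- function(scan, path) {
  stopifnot(inherits(scan, "spectral_scan"))
  if (nrow(scan$intensities) == 0L) stop("refusing to write an empty scan")
  fmt <- function(v) paste(sprintf("%.17g", v), collapse = "\t")
  lines <- c(fmt(scan$wavenumbers),
             apply(scan$intensities, 1L, fmt))
  writeLines(lines, path)
  invisible(path)
}

#' Average repeated measurements per scan point
#'
#' Repeated spectra of the same point are replaced by their arithmetic mean,
#' suppressing random machine noise before any imaging step.
#'
#' @param scan a [spectral_scan()].
#' @return A [spectral_scan()] with `repeats == 1`.
#' @export
average_repeats <- function(scan) {
  stopifnot(inherits(scan, "spectral_scan"))
  if (scan$repeats == 1L) return(scan)
  n_pts <- scan$grid_rows * scan$grid_cols
  grp <- rep(seq_len(n_pts), each = scan$repeats)
  avg <- rowsum(scan$intensities, grp, reorder = TRUE) / scan$repeats
  spectral_scan(scan$wavenumbers, avg, scan$grid_rows, scan$grid_cols, 1L)
}

#' Spectral band window
#'
#' A closed wavenumber interval `[lo, hi]` used to restrict imaging and
#' variance statistics to a sub-band (for cells, 2750-3050 cm^-1, the
#' CH-stretch region, carries most of the signal).
#'
#' @param lo,hi band bounds in cm^-1, `lo < hi`.
#' @return An object of class `band_window`.
#' @export
band_window <- function(lo, hi) {
  lo <- as.numeric(lo); hi <- as.numeric(hi)
  if (!is.finite(lo) || !is.finite(hi) || lo >= hi)
    stop("band_window needs finite lo < hi")
  structure(list(lo = lo, hi = hi), class = "band_window")
}

#' @export
print.band_window <- function(x, ...) {
  cat(sprintf("band_window: [%g, %g] cm^-1\n", x$lo, x$hi)); invisible(x)
}

# indices of the wavenumber axis inside a band (closed interval)
band_indices <- function(wavenumbers, band) {
  stopifnot(inherits(band, "band_window"))
  idx <- which(wavenumbers >= band$lo & wavenumbers <= band$hi)
  if (!length(idx))
    stop(sprintf("band [%g, %g] does not intersect the wavenumber axis",
                 band$lo, band$hi))
  idx
}

#' Band covering a scan's whole wavenumber axis
#'
#' Convenience for full-band imaging.
#'
#' @param scan a [spectral_scan()].
#' @return A [band_window()] spanning the axis.
#' @export
full_band <- function(scan) {
  band_window(min(scan$wavenumbers) - 1e-9, max(scan$wavenumbers) + 1e-9)
}
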