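# Plain-text Netpbm output.  The environment ships no PNG codec for R, so
# grayscale rasters go out as ASCII PGM (P2) and color as ASCII PPM (P3);
# both are widely readable and byte-stable across runs.

#' Write a grayscale image as ASCII PGM
#'
#' Values are rounded half-up to integers and clamped to \[0, 255\].
#'
#' @param img numeric matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pgm <- function(img, path) {
  img <- as.matrix(img)
  q <- pmin(pmax(as.integer(floor(img + 0.5)), 0L), 255L)
  dim(q) <- dim(img)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), "255"), con, sep = "\n")
  writeLines(apply(q, 1L, paste, collapse = " "), con, sep = "\n")
  invisible(path)
}

#' Write an RGB image as ASCII PPM
#'
#' @param rgb integer array `h x w x 3` with values in \[0, 255\].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ppm <- function(rgb, path) {
  stopifnot(length(dim(rgb)) == 3L, dim(rgb)[3L] == 3L)
  q <- pmin(pmax(as.integer(floor(rgb + 0.5)), 0L), 255L)
  dim(q) <- dim(rgb)
  h <- dim(q)[1L]; w <- dim(q)[2L]
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("P3", paste(w, h), "255"), con, sep = "\n")
  rows <- vapply(seq_len(h), function(i) {
    tri <- rbind(q[i, , 1L], q[i, , 2L], q[i, , 3L])
    paste(as.vector(tri), collapse = " ")
  }, character(1L))
  writeLines(rows, con, sep = "\n")
  invisible(path)
}

#' Read ASCII PGM / PPM images
#'
#' Minimal readers for the formats written by [write_pgm()] and
#' [write_ppm()] (no comment support).
#'
#' @param path file to read.
#' @return `read_pgm`: numeric matrix; `read_ppm`: integer `h x w x 3`
#'   array.
#' @export
read_pgm <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE)
  if (toks[[1L]] != "P2") stop("not an ASCII PGM file")
  w <- as.integer(toks[[2L]]); h <- as.integer(toks[[3L]])
  vals <- as.numeric(toks[-(1:4)])
  if (length(vals) != w * h) stop("corrupt PGM payload")
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

#' @rdname read_pgm
#' @export
read_ppm <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE)
  if (toks[[1L]] != "P3") stop("not an ASCII PPM file")
  w <- as.integer(toks[[2L]]); h <- as.integer(toks[[3L]])
  vals <- as.integer(toks[-(1:4)])
  if (length(vals) != 3L * w * h) stop("corrupt PPM payload")
  px <- matrix(vals, ncol = 3L, byrow = TRUE)
  out <- array(0L, c(h, w, 3L))
  idx <- 0L
  for (i in seq_len(h)) {
    out[i, , 1L] <- px[idx + seq_len(w), 1L]
    out[i, , 2L] <- px[idx + seq_len(w), 2L]
    out[i, , 3L] <- px[idx + seq_len(w), 3L]
    idx <- idx + w
  }
  out
}
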