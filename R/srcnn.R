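#' Three-layer super-resolution network weights
#'
#' The network maps a bicubic-upscaled grayscale image (values in \[0, 1\])
#' to a restored image of the same size: 64 feature-extraction kernels of
#' 9 x 9, 32 mapping kernels of 5 x 5 x 64, and one 5 x 5 x 32
#' reconstruction kernel, ReLU after the first two layers, symmetric
#' boundary extension everywhere so spatial dimensions are preserved.
#'
#' @param W1 array `9 x 9 x 1 x 64`.
#' @param B1 numeric length 64.
#' @param W2 array `5 x 5 x 64 x 32`.
#' @param B2 numeric length 32.
#' @param W3 array `5 x 5 x 32 x 1`.
#' @param B3 numeric length 1.
#' @return An object of class `srcnn_weights`.
#' @export
srcnn_weights <- function(W1, B1, W2, B2, W3, B3) {
  chk <- function(x, d, nm) {
    x <- as.array(x)
    if (!identical(dim(x), as.integer(d)))
      stop(sprintf("%s must have shape %s", nm, paste(d, collapse = "x")))
    if (any(!is.finite(x))) stop(nm, " contains non-finite values")
    storage.mode(x) <- "double"
    x
  }
  chkb <- function(x, n, nm) {
    x <- as.numeric(x)
    if (length(x) != n) stop(sprintf("%s must have length %d", nm, n))
    if (any(!is.finite(x))) stop(nm, " contains non-finite values")
    x
  }
  structure(list(W1 = chk(W1, c(9, 9, 1, 64), "W1"),
                 B1 = chkb(B1, 64, "B1"),
                 W2 = chk(W2, c(5, 5, 64, 32), "W2"),
                 B2 = chkb(B2, 32, "B2"),
                 W3 = chk(W3, c(5, 5, 32, 1), "W3"),
                 B3 = chkb(B3, 1, "B3")),
            class = "srcnn_weights")
}

#' @export
print.srcnn_weights <- function(x, ...) {
  cat("srcnn_weights: 64x9x9 -> 32x5x5x64 -> 1x5x5x32, ReLU, symmetric pad\n")
  invisible(x)
}

#' Identity-configured network weights
#'
#' Delta kernels routing the input through channel 1 of each layer with zero
#' biases: the forward pass reproduces its input exactly for values in
#' \[0, 1\].  Useful for ablations (pure iterated bicubic upscaling) and as
#' a reference point for the training initialization.
#'
#' @return An [srcnn_weights()] object.
#' @export
srcnn_identity_weights <- function() {
  W1 <- array(0, c(9, 9, 1, 64)); W1[5, 5, 1, 1] <- 1
  W2 <- array(0, c(5, 5, 64, 32)); W2[3, 3, 1, 1] <- 1
  W3 <- array(0, c(5, 5, 32, 1)); W3[3, 3, 1, 1] <- 1
  srcnn_weights(W1, rep(0, 64), W2, rep(0, 32), W3, 0)
}

# raw network on a [0,1] matrix; returns intermediates when keep = TRUE
srcnn_infer01 <- function(x01, w, keep = FALSE) {
  x <- array(x01, c(nrow(x01), ncol(x01), 1L))
  if (!keep) {
    f1 <- conv2d_sym(x, w$W1, w$B1, TRUE)
    f2 <- conv2d_sym(f1, w$W2, w$B2, TRUE)
    f3 <- conv2d_sym(f2, w$W3, w$B3, FALSE)
    return(f3[, , 1L])
  }
  z1 <- conv2d_sym(x, w$W1, w$B1, FALSE); a1 <- pmax(z1, 0)
  dim(a1) <- dim(z1)
  z2 <- conv2d_sym(a1, w$W2, w$B2, FALSE); a2 <- pmax(z2, 0)
  dim(a2) <- dim(z2)
  z3 <- conv2d_sym(a2, w$W3, w$B3, FALSE)
  list(x = x, z1 = z1, a1 = a1, z2 = z2, a2 = a2, z3 = z3)
}

#' Forward pass of the super-resolution network
#'
#' The image is scaled to \[0, 1\], passed through the three convolution
#' layers (symmetric boundary extension keeps the spatial size), clipped to
#' \[0, 1\] and rescaled to \[0, 255\].
#'
#' @param img numeric matrix in \[0, 255\], at least 9 x 9.
#' @param w an [srcnn_weights()] object.
#' @return Matrix of the same shape in \[0, 255\].
#' @export
srcnn_forward <- function(img, w) {
  stopifnot(inherits(w, "srcnn_weights"))
  img <- as.matrix(img)
  if (nrow(img) < 9L || ncol(img) < 9L) stop("image must be at least 9x9")
  out <- srcnn_infer01(img / 255, w)
  pmin(pmax(out, 0), 1) * 255
}

#' Iterated super-resolution to a target size
#'
#' Repeats (bicubic x`scale` upscale, then network restoration) until the
#' smaller image side reaches `target_min` pixels; a 20 x 20 peak image
#' reaches 320 x 320 in four doublings.
#'
#' @param img numeric matrix in \[0, 255\], at least 10 x 10.
#' @param w an [srcnn_weights()] object, or `NULL` for bicubic-only
#'   upscaling (ablation).
#' @param target_min target minimum side in pixels (default 320).
#' @param scale integer upscale factor per iteration (default 2).
#' @return Upscaled matrix with `min(dim) >= target_min` (unchanged if
#'   already large enough).
#' @export
superresolve <- function(img, w, target_min = 320L, scale = 2L) {
  img <- as.matrix(img)
  if (nrow(img) < 10L || ncol(img) < 10L) stop("image must be at least 10x10")
  scale <- as.integer(scale)
  stopifnot(scale >= 2L, target_min >= 1L)
  while (min(dim(img)) < target_min) {
    img <- resize_gray(img, nrow(img) * scale, ncol(img) * scale, "bicubic")
    if (!is.null(w)) img <- srcnn_forward(img, w)
  }
  img
}

#' Train the super-resolution network on patch pairs
#'
#' Desk-scale replacement for large-corpus pre-training: full-batch Adam on
#' the mean squared error between the network output for bicubic-upscaled
#' low-resolution patches and their high-resolution originals, both on the
#' \[0, 1\] scale.  Weights start at the identity configuration plus small
#' seeded Gaussian perturbations, so the initial network reproduces the
#' bicubic baseline and training can only improve on it.  Fully
#' deterministic given `seed`.
#'
#' @param patches list of pairs; each element a list with `lr` (low-res
#'   matrix) and `hr` (high-res matrix, at least 33 x 33), gray values in
#'   \[0, 255\].
#' @param seed integer RNG seed.
#' @param epochs number of full-batch update steps.
#' @param lr_rate Adam step size.
#' @return An [srcnn_weights()] object with attribute `loss_history`, the
#'   per-epoch training MSE (epoch 0 = initialization).
#' @export
train_srcnn <- function(patches, seed = 1L, epochs = 40L, lr_rate = 1e-3) {
  if (!is.list(patches) || length(patches) == 0L)
    stop("training set is empty")
  xs <- vector("list", length(patches))
  ys <- vector("list", length(patches))
  for (k in seq_along(patches)) {
    p <- patches[[k]]
    if (is.null(p$lr) || is.null(p$hr)) stop("each patch needs $lr and $hr")
    hr <- as.matrix(p$hr)
    if (nrow(hr) < 33L || ncol(hr) < 33L)
      stop("high-res patches must be at least 33x33")
    xs[[k]] <- resize_gray(as.matrix(p$lr), nrow(hr), ncol(hr), "bicubic") / 255
    ys[[k]] <- hr / 255
  }

  set.seed(as.integer(seed))
  w <- srcnn_identity_weights()
  # perturbation small enough that the starting network is numerically the
  # bicubic baseline; symmetry is still broken for the extra channels
  w$W1 <- w$W1 + array(rnorm(length(w$W1), 0, 1e-4), dim(w$W1))
  w$W2 <- w$W2 + array(rnorm(length(w$W2), 0, 1e-4), dim(w$W2))
  w$W3 <- w$W3 + array(rnorm(length(w$W3), 0, 1e-4), dim(w$W3))

  params <- c("W1", "B1", "W2", "B2", "W3", "B3")
  m <- lapply(params, function(p) array(0, dim(as.array(w[[p]]))))
  v <- m
  names(m) <- names(v) <- params
  b1 <- 0.9; b2 <- 0.999; adam_eps <- 1e-8

  batch_loss_grads <- function(w) {
    g <- lapply(params, function(p) array(0, dim(as.array(w[[p]]))))
    names(g) <- params
    loss <- 0
    for (k in seq_along(xs)) {
      st <- srcnn_infer01(xs[[k]], w, keep = TRUE)
      resid <- st$z3 - array(ys[[k]], dim(st$z3))
      n_el <- length(resid)
      loss <- loss + mean(resid^2)
      dz3 <- 2 * resid / n_el
      bk3 <- conv2d_sym_backward(st$a2, w$W3, dz3)
      da2 <- bk3$dx; da2[st$z2 <= 0] <- 0
      bk2 <- conv2d_sym_backward(st$a1, w$W2, da2)
      da1 <- bk2$dx; da1[st$z1 <= 0] <- 0
      bk1 <- conv2d_sym_backward(st$x, w$W1, da1)
      g$W1 <- g$W1 + bk1$dw; g$B1 <- g$B1 + bk1$db
      g$W2 <- g$W2 + bk2$dw; g$B2 <- g$B2 + bk2$db
      g$W3 <- g$W3 + bk3$dw; g$B3 <- g$B3 + bk3$db
    }
    nb <- length(xs)
    list(loss = loss / nb, grads = lapply(g, function(x) x / nb))
  }

  history <- numeric(epochs + 1L)
  for (t in seq_len(epochs)) {
    bg <- batch_loss_grads(w)
    history[t] <- bg$loss
    for (p in params) {
      gp <- bg$grads[[p]]
      m[[p]] <- b1 * m[[p]] + (1 - b1) * gp
      v[[p]] <- b2 * v[[p]] + (1 - b2) * gp^2
      mhat <- m[[p]] / (1 - b1^t)
      vhat <- v[[p]] / (1 - b2^t)
      w[[p]] <- w[[p]] - lr_rate * mhat / (sqrt(vhat) + adam_eps)
    }
  }
  history[epochs + 1L] <- batch_loss_grads(w)$loss
  out <- srcnn_weights(w$W1, w$B1, w$W2, w$B2, w$W3, w$B3)
  attr(out, "loss_history") <- history
  out
}

#' Save network weights as plain text
#'
#' A flat text container: a magic line, then per tensor a header line
#' (`name` and dimensions) followed by the values with 17 significant
#' digits, so a round trip is bit-exact.
#'
#' @param w an [srcnn_weights()] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_weights <- function(w, path) {
  stopifnot(inherits(w, "srcnn_weights"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("ramanpc-srcnn-weights v1", con)
  for (nm in c("W1", "B1", "W2", "B2", "W3", "B3")) {
    x <- w[[nm]]
    d <- if (is.null(dim(x))) length(x) else dim(x)
    writeLines(paste(nm, paste(d, collapse = " ")), con)
    vals <- sprintf("%.17g", as.numeric(x))
    chunks <- split(vals, ceiling(seq_along(vals) / 500))
    writeLines(vapply(chunks, paste, character(1L), collapse = " "), con)
  }
  invisible(path)
}

#' @rdname save_weights
#' @export
load_weights <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 1L || lines[[1L]] != "ramanpc-srcnn-weights v1")
    stop("not a recognized weight file")
  pos <- 2L
  out <- list()
  expected <- list(W1 = c(9, 9, 1, 64), B1 = 64, W2 = c(5, 5, 64, 32),
                   B2 = 32, W3 = c(5, 5, 32, 1), B3 = 1)
  for (nm in names(expected)) {
    if (pos > length(lines)) stop("truncated weight file at ", nm)
    hdr <- strsplit(trimws(lines[[pos]]), " +")[[1L]]
    if (hdr[[1L]] != nm) stop("expected tensor ", nm, ", found ", hdr[[1L]])
    d <- as.integer(hdr[-1L])
    if (!identical(d, as.integer(expected[[nm]])))
      stop("shape mismatch for ", nm)
    n <- prod(d)
    pos <- pos + 1L
    vals <- numeric(0)
    while (length(vals) < n) {
      if (pos > length(lines)) stop("truncated weight file in ", nm)
      vals <- c(vals, as.numeric(strsplit(trimws(lines[[pos]]), " +")[[1L]]))
      pos <- pos + 1L
    }
    if (length(vals) != n || any(is.na(vals)))
      stop("corrupt values for ", nm)
    out[[nm]] <- if (length(d) > 1L) array(vals, d) else vals
  }
  srcnn_weights(out$W1, out$B1, out$W2, out$B2, out$W3, out$B3)
}

# package-local cache for the default trained weights
.ramanpc_cache <- new.env(parent = emptyenv())

#' Default deterministically trained network weights
#'
#' Trains the network once per session on seeded synthetic cell-like
#' patches (see [make_training_patches()]) and caches the result.  The
#' recipe is fixed, so every session reproduces the same weights.
#'
#' @param epochs training epochs (default 40).
#' @param n_patches number of patch pairs (default 6).
#' @return An [srcnn_weights()] object.
#' @export
default_srcnn_weights <- function(epochs = 40L, n_patches = 6L) {
  key <- sprintf("w_%d_%d", epochs, n_patches)
  if (!is.null(.ramanpc_cache[[key]])) return(.ramanpc_cache[[key]])
  patches <- make_training_patches(n_patches, size = 33L, seed = 20190920L)
  w <- train_srcnn(patches, seed = 20190920L, epochs = epochs)
  .ramanpc_cache[[key]] <- w
  w
}

#' Synthetic cell-like training patches for the network
#'
#' High-resolution patches are sums of random elliptical Gaussian blobs on a
#' dark background (mimicking bright cell bodies on a peak image), stretched
#' to \[0, 255\]; the low-resolution partner is a 2x bilinear downscale.
#'
#' @param n number of pairs.
#' @param size high-resolution patch side (odd, at least 33).
#' @param seed RNG seed.
#' @return List of `list(lr =, hr =)` pairs.
#' @export
make_training_patches <- function(n, size = 33L, seed = 1L) {
  stopifnot(n >= 1L, size >= 33L)
  set.seed(as.integer(seed))
  half <- as.integer(ceiling(size / 2))
  lapply(seq_len(n), function(k) {
    hr <- matrix(0, size, size)
    for (blob in seq_len(sample(2:4, 1L))) {
      cy <- runif(1, 0.2, 0.8) * size
      cx <- runif(1, 0.2, 0.8) * size
      sy <- runif(1, 0.08, 0.25) * size
      sx <- runif(1, 0.08, 0.25) * size
      amp <- runif(1, 0.4, 1)
      g <- outer(seq_len(size), seq_len(size), function(i, j)
        amp * exp(-((i - cy)^2 / (2 * sy^2) + (j - cx)^2 / (2 * sx^2))))
      hr <- hr + g
    }
    hr <- normalize_gray(hr)
    list(lr = resize_gray(hr, half, half, "bilinear"), hr = hr)
  })
}
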