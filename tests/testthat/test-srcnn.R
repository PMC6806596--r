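test_that("weight constructor enforces shapes", {
  w <- srcnn_identity_weights()
  expect_s3_class(w, "srcnn_weights")
  expect_error(srcnn_weights(array(0, c(9, 9, 1, 63)), rep(0, 64),
                             w$W2, w$B2, w$W3, w$B3), "W1")
  expect_error(srcnn_weights(w$W1, rep(0, 10), w$W2, w$B2, w$W3, w$B3), "B1")
  w$W2[1] <- NA
  expect_error(srcnn_weights(w$W1, w$B1, w$W2, w$B2, w$W3, w$B3),
               "non-finite")
})

test_that("forward pass preserves spatial dimensions", {
  w <- srcnn_identity_weights()
  for (side in c(20L, 33L, 64L)) {
    img <- matrix(runif(side * side, 0, 255), side, side)
    expect_equal(dim(srcnn_forward(img, w)), c(side, side))
  }
  # non-square
  img <- matrix(runif(20 * 45, 0, 255), 20, 45)
  expect_equal(dim(srcnn_forward(img, w)), c(20L, 45L))
  expect_error(srcnn_forward(matrix(0, 5, 5), w), "9x9")
})

test_that("bias-only network returns the constant bias", {
  w <- srcnn_identity_weights()
  w0 <- srcnn_weights(array(0, dim(w$W1)), rep(0, 64),
                      array(0, dim(w$W2)), rep(0, 32),
                      array(0, dim(w$W3)), 0.5)
  img <- matrix(runif(400, 0, 255), 20, 20)
  expect_equal(srcnn_forward(img, w0), matrix(0.5 * 255, 20, 20),
               tolerance = 1e-12)
})

test_that("identity configuration reproduces the input exactly", {
  w <- srcnn_identity_weights()
  set.seed(101)
  img <- matrix(runif(400, 0, 255), 20, 20)
  expect_equal(srcnn_forward(img, w), img, tolerance = 1e-12)
})

test_that("translation equivariance holds on interior pixels", {
  w <- srcnn_identity_weights()
  set.seed(7)
  # add mild random weights so the network is not trivial
  w$W1 <- w$W1 + array(rnorm(length(w$W1), 0, 0.01), dim(w$W1))
  w$W3 <- w$W3 + array(rnorm(length(w$W3), 0, 0.01), dim(w$W3))
  period <- 8L
  tile <- matrix(runif(period * period, 0, 255), period, period)
  big <- tile[rep(1:period, 6), rep(1:period, 6)]      # 48x48 periodic
  out <- srcnn_forward(big, w)
  inner <- 17:(17 + period - 1)
  expect_equal(out[inner, inner], out[inner + period, inner + period],
               tolerance = 1e-9)
})

test_that("superresolve reaches the target size and composes with bicubic", {
  wid <- srcnn_identity_weights()
  img <- matrix(runif(400, 0, 255), 20, 20)
  out <- superresolve(img, wid, target_min = 320)
  expect_equal(dim(out), c(320L, 320L))
  # single doubling when close
  img160 <- matrix(runif(160 * 160, 0, 255), 160, 160)
  expect_equal(dim(superresolve(img160, wid, 320)), c(320L, 320L))
  # identity weights equal pure iterated bicubic (forward clamps to the
  # gray range each iteration, so the reference clamps per iteration too:
  # bicubic overshoots [0,255] slightly)
  pure <- img
  for (k in 1:4) pure <- pmin(pmax(resize_gray(pure, nrow(pure) * 2,
                                               ncol(pure) * 2, "bicubic"),
                                   0), 255)
  expect_lt(max(abs(out - pure)), 1e-6)
  # already large input passes through
  expect_identical(superresolve(img160, wid, 100), img160)
})

test_that("training decreases the loss deterministically", {
  patches <- make_training_patches(2, size = 33, seed = 5)
  # small step size: near the identity start the bicubic baseline is almost
  # optimal on smooth patches, and default-size Adam steps overshoot first
  w1 <- train_srcnn(patches, seed = 9, epochs = 10, lr_rate = 3e-5)
  w2 <- train_srcnn(patches, seed = 9, epochs = 10, lr_rate = 3e-5)
  h1 <- attr(w1, "loss_history")
  expect_identical(h1, attr(w2, "loss_history"))       # bitwise determinism
  expect_identical(w1$W2, w2$W2)
  expect_lt(h1[length(h1)], h1[1])                     # loss decreased
  expect_error(train_srcnn(list(), seed = 1), "empty")
  expect_error(train_srcnn(list(list(lr = matrix(0, 8, 8),
                                     hr = matrix(0, 16, 16))), seed = 1),
               "33x33")
})

test_that("weights round-trip through the text container bitwise", {
  set.seed(13)
  w <- srcnn_identity_weights()
  w$W1 <- w$W1 + array(rnorm(length(w$W1)), dim(w$W1))
  w$W2 <- w$W2 + array(rnorm(length(w$W2)), dim(w$W2))
  w$W3 <- w$W3 + array(rnorm(length(w$W3)), dim(w$W3))
  w$B1 <- rnorm(64); w$B2 <- rnorm(32); w$B3 <- rnorm(1)
  w <- srcnn_weights(w$W1, w$B1, w$W2, w$B2, w$W3, w$B3)
  path <- withr::local_tempfile(fileext = ".txt")
  save_weights(w, path)
  back <- load_weights(path)
  expect_identical(back$W1, w$W1)
  expect_identical(back$W2, w$W2)
  expect_identical(back$B3, w$B3)
  # forward results agree bitwise
  img <- matrix(runif(400, 0, 255), 20, 20)
  expect_identical(srcnn_forward(img, back), srcnn_forward(img, w))
  # truncation and corruption are detected
  lines <- readLines(path)
  writeLines(lines[1:3], path)
  expect_error(load_weights(path), "truncated|corrupt|shape")
  writeLines(c("junk"), path)
  expect_error(load_weights(path), "not a recognized")
})
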