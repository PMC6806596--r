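make_peak_scan <- function() {
  # 1 point, spectrum with an isolated peak neighborhood (10,20,500,20,10)
  wn <- seq(100, 1000, length.out = 9)
  spec <- c(1, 1, 10, 20, 500, 20, 10, 1, 1)
  spectral_scan(wn, matrix(spec, 1), 1, 1, 1)
}

test_that("extract_peak_image takes the band maximum and symmetric means", {
  sc <- make_peak_scan()
  band <- full_band(sc)
  expect_equal(extract_peak_image(sc, band, 0)[1, 1], 500)
  # mean of peak and 2 neighbors per side: (10+20+500+20+10)/5 = 112
  expect_equal(extract_peak_image(sc, band, 4)[1, 1], 112)
  # constant spectrum gives the constant for any n_sym
  scc <- spectral_scan(sc$wavenumbers, matrix(7, 1, 9), 1, 1, 1)
  for (ns in c(0, 4, 8, 12))
    expect_equal(extract_peak_image(scc, band, ns)[1, 1], 7)
  # n_sym clipped at the band edge: peak at channel 1
  sc_edge <- spectral_scan(sc$wavenumbers,
                           matrix(c(100, 10, 4, rep(1, 6)), 1), 1, 1, 1)
  expect_equal(extract_peak_image(sc_edge, band, 4)[1, 1], mean(c(100, 10, 4)))
  expect_error(extract_peak_image(sc, band, 3), "n_sym")
})

test_that("peak image is laid out row-major and permutation-equivariant", {
  wn <- c(1, 2)
  vals <- c(10, 20, 30, 40, 50, 60)             # point k has peak value
  m <- cbind(vals, vals / 2)
  sc <- spectral_scan(wn, m, 2, 3, 1)
  img <- extract_peak_image(sc, full_band(sc), 0)
  expect_equal(img, matrix(vals, 2, 3, byrow = TRUE))
  # permuting scan points permutes pixels identically
  perm <- c(4, 1, 6, 2, 5, 3)
  scp <- spectral_scan(wn, m[perm, ], 2, 3, 1)
  imgp <- extract_peak_image(scp, full_band(scp), 0)
  expect_equal(as.vector(t(imgp)), vals[perm])
})

test_that("peak ties resolve to the lowest wavenumber", {
  wn <- c(1, 2, 3)
  sc <- spectral_scan(wn, matrix(c(5, 9, 9), 1), 1, 1, 1)
  # with n_sym = 4 the mean is taken around the FIRST maximal channel (2):
  # window clipped to channels 1..3 -> mean(5,9,9)
  expect_equal(extract_peak_image(sc, full_band(sc), 4)[1, 1], mean(c(5, 9, 9)))
})

test_that("normalize_gray stretches to [0,255] and zeros constants", {
  expect_equal(normalize_gray(matrix(0:255, 16)), matrix(0:255, 16),
               ignore_attr = TRUE)
  expect_equal(sort(unique(as.vector(normalize_gray(matrix(c(10, 20), 1))))),
               c(0, 255))
  expect_true(all(normalize_gray(matrix(42, 3, 3)) == 0))
  set.seed(5)
  x <- matrix(rnorm(100), 10)
  y <- normalize_gray(x)
  expect_equal(range(y), c(0, 255))
})

test_that("band_variance_map computes population variance and n_above", {
  wn <- c(1, 2)
  sc <- spectral_scan(wn, rbind(c(0, 2000), c(5, 5)), 2, 1, 1)
  vm <- band_variance_map(sc, full_band(sc), 1000)
  # population variance of (0, 2000) = 1e6
  expect_equal(vm$values[1, 1], 1e6)
  expect_equal(vm$values[2, 1], 0)
  expect_equal(vm$n_above, 1L)
  # constant spectra -> all zero
  scc <- spectral_scan(wn, matrix(3, 4, 2), 2, 2, 1)
  vmc <- band_variance_map(scc, full_band(scc), 1000)
  expect_true(all(vmc$values == 0) && vmc$n_above == 0L)
  # infinite threshold -> none counted
  expect_equal(band_variance_map(sc, full_band(sc), Inf)$n_above, 0L)
  # < 2 channels is an error
  sc1 <- make_tiny_scan(n_chan = 10)
  narrow <- band_window(sc1$wavenumbers[1] - 0.1, sc1$wavenumbers[1] + 0.1)
  expect_error(band_variance_map(sc1, narrow), "at least 2 channels")
})

test_that("n_above is monotone non-increasing in the threshold", {
  sc <- make_tiny_scan(grid_rows = 4, grid_cols = 4, n_chan = 32, seed = 11)
  band <- full_band(sc)
  ths <- c(0, 10, 100, 1e3, 1e4, 1e5, 1e6)
  counts <- vapply(ths, function(t)
    band_variance_map(sc, band, t)$n_above, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("summarize_sigma2 supports mean, median and max", {
  wn <- c(1, 2)
  sc <- spectral_scan(wn, rbind(c(0, 2000), c(5, 5)), 2, 1, 1)
  vm <- band_variance_map(sc, full_band(sc))
  expect_equal(summarize_sigma2(vm, "mean"), 5e5)
  expect_equal(summarize_sigma2(vm, "max"), 1e6)
  expect_equal(summarize_sigma2(vm, "median"), 5e5)
})
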