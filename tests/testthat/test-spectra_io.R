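test_that("read_scan parses a minimal well-formed file and validates geometry", {
  path <- withr::local_tempfile(fileext = ".tsv")
  wn <- c(100, 200, 300)
  rows <- rbind(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9), c(10, 11, 12))
  writeLines(c(paste(wn, collapse = "\t"),
               apply(rows, 1, paste, collapse = "\t")), path)
  sc <- read_scan(path, 2, 2, 1)
  expect_s3_class(sc, "spectral_scan")
  expect_equal(sc$intensities, rows, ignore_attr = TRUE)
  expect_equal(sc$wavenumbers, wn)
  # wrong declared geometry
  expect_error(read_scan(path, 3, 3, 1), "geometry")
  # ragged row
  writeLines(c("100\t200\t300", "1\t2\t3", "4\t5"), path)
  expect_error(read_scan(path, 1, 2, 1), "ragged")
  # non-numeric cell
  writeLines(c("100\t200", "1\tx"), path)
  expect_error(read_scan(path, 1, 1, 1), "parse")
  # comma dialect auto-detected
  writeLines(c("100,200", "1,2"), path)
  expect_equal(read_scan(path, 1, 1, 1)$intensities[1, ], c(1, 2))
})

test_that("spectral_scan enforces its invariants", {
  wn <- c(1, 2, 3)
  ok <- matrix(1, 4, 3)
  expect_error(spectral_scan(c(3, 2, 1), ok, 2, 2), "increasing")
  expect_error(spectral_scan(wn, matrix(1, 3, 3), 2, 2), "geometry")
  expect_error(spectral_scan(wn, matrix(-1, 4, 3), 2, 2), "non-negative")
  expect_error(spectral_scan(wn, matrix(Inf, 4, 3), 2, 2), "finite")
})

test_that("average_repeats averages consecutive rows per point", {
  # identity at repeats = 1
  sc1 <- make_tiny_scan(repeats = 1L)
  expect_identical(average_repeats(sc1), sc1)
  # hand-checked mean of two repeats
  wn <- c(10, 20)
  m <- rbind(c(100, 0), c(200, 4),   # point 1: repeats (100,0) and (200,4)
             c(7, 7), c(7, 7))       # point 2: equal repeats
  sc <- spectral_scan(wn, m, 1, 2, repeats = 2)
  avg <- average_repeats(sc)
  expect_equal(avg$repeats, 1L)
  expect_equal(avg$intensities[1, ], c(150, 2))
  expect_equal(avg$intensities[2, ], c(7, 7))
  # idempotence
  expect_equal(average_repeats(avg), avg)
})

test_that("average_repeats commutes with per-channel linear rescaling", {
  sc <- make_tiny_scan(grid_rows = 3, grid_cols = 2, repeats = 3, seed = 1)
  scale <- runif(length(sc$wavenumbers), 0.5, 2)
  rescaled <- spectral_scan(sc$wavenumbers,
                            sweep(sc$intensities, 2, scale, "*"),
                            sc$grid_rows, sc$grid_cols, sc$repeats)
  a <- average_repeats(rescaled)$intensities
  b <- sweep(average_repeats(sc)$intensities, 2, scale, "*")
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("write_scan / read_scan round-trips numerically", {
  sc <- make_tiny_scan(grid_rows = 2, grid_cols = 2, repeats = 2, seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_scan(sc, path)
  back <- read_scan(path, 2, 2, 2)
  expect_equal(back$intensities, sc$intensities,
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(back$wavenumbers, sc$wavenumbers, tolerance = 1e-9)
  # phantom output round-trips too
  ph <- generate_phantom(phantom_spec(grid_rows = 3, grid_cols = 3,
                                      n_channels = 32, cells = list(
                                        list(row = 2, col = 2, a = 1, b = 1)),
                                      seed = 7))
  write_scan(ph$scan, path)
  back <- read_scan(path, 3, 3, 2)
  expect_equal(back$intensities, ph$scan$intensities,
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("band helpers select channels and reject empty intersections", {
  sc <- make_tiny_scan(n_chan = 10)
  expect_error(band_window(5, 5), "lo < hi")
  expect_error(extract_peak_image(sc, band_window(5000, 6000)),
               "does not intersect")
  fb <- full_band(sc)
  expect_length(ramanpc:::band_indices(sc$wavenumbers, fb), 10L)
})
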