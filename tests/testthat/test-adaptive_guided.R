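test_that("guided filter matches the double-loop oracle on random images", {
  set.seed(3)
  for (rep in 1:6) {
    p <- matrix(runif(256), 16, 16)
    for (r in 1:3) {
      for (eps in c(0.01, 0.12)) {
        expect_lt(max(abs(guided_filter(p, r, eps) -
                          oracle_guided(p, r, eps))), 1e-9)
      }
    }
  }
})

test_that("guided filter limits: constants pass through, eps -> 0 is identity", {
  const <- matrix(5, 12, 12)
  expect_equal(guided_filter(const, 2, 0.12), const, tolerance = 1e-12)
  set.seed(4)
  p <- matrix(runif(144), 12, 12)
  expect_lt(max(abs(guided_filter(p, 2, 1e-12) - p)), 1e-6)
  expect_error(guided_filter(matrix(1, 3, 3), 2, 0.1), "smaller")
})

test_that("guided filter output is bounded by the input range", {
  set.seed(6)
  for (rep in 1:5) {
    p <- matrix(runif(400, -3, 7), 20, 20)
    q <- guided_filter(p, 2, 0.05)
    expect_gte(min(q), min(p) - 1e-9)
    expect_lte(max(q), max(p) + 1e-9)
  }
})

test_that("guided filter applies per channel on color arrays", {
  set.seed(8)
  rgb <- array(runif(3 * 144), c(12, 12, 3))
  out <- guided_filter(rgb, 1, 0.05)
  for (ch in 1:3)
    expect_equal(out[, , ch], guided_filter(rgb[, , ch], 1, 0.05))
})

test_that("adaptive_params reproduces the built-in model arithmetic", {
  # intercepts at the origin
  p0 <- adaptive_params(0, 0, 0)
  expect_identical(p0$omega, 3.1181)
  expect_identical(p0$eps, 44.2304)
  # hand arithmetic on the built-in coefficients
  p <- adaptive_params(400, 100, 2000)
  expect_equal(p$omega, 0.0113 * 400 - 0.0056 * 100 + 0.0001 * 2000 + 3.1181)
  expect_equal(p$eps, -0.0797 * 400 + 0.1210 * 100 - 0.0001 * 2000 + 44.2304)
  expect_equal(p$omega, 7.2781)
  expect_equal(p$eps, 24.2504)
  # window-width rounding rule
  expect_equal(p$width, 7L)
  expect_equal(p$r, 3L)
  expect_equal(adaptive_params(0, 0, 0)$width, 3L)
  # eps floor on the [0,1] scale
  big <- adaptive_params(1000, 0, 0)           # raw eps would be negative
  expect_gte(big$eps01, 1e-4)
  expect_error(adaptive_params(10, 20, 0), "exceed")
})

test_that("adaptive_params is affine in each argument", {
  co <- builtin_adaptive_coefficients()
  base <- adaptive_params(100, 50, 500, co)
  d_n1 <- adaptive_params(101, 50, 500, co)$omega - base$omega
  d_n2 <- adaptive_params(100, 51, 500, co)$omega - base$omega
  d_s2 <- adaptive_params(100, 50, 501, co)$omega - base$omega
  expect_lt(abs(d_n1 - co$a1), 1e-12)
  expect_lt(abs(d_n2 - co$b1), 1e-12)
  expect_lt(abs(d_s2 - co$c1), 1e-12)
  e_n1 <- adaptive_params(101, 50, 500, co)$eps - base$eps
  expect_lt(abs(e_n1 - co$a2), 1e-12)
})

test_that("fit_coefficients recovers known coefficients from clean data", {
  set.seed(19)
  truth <- adaptive_coefficients(a1 = 0.02, b1 = -0.01, c1 = 2e-4, d1 = 2.5,
                                 a2 = -0.05, b2 = 0.2, c2 = -3e-4, d2 = 40)
  n <- 10
  N1 <- sample(50:500, n)
  N2 <- pmin(N1, sample(0:200, n))
  s2 <- runif(n, 0, 5000)
  data <- data.frame(
    N1 = N1, N2 = N2, sigma2 = s2,
    omega = truth$a1 * N1 + truth$b1 * N2 + truth$c1 * s2 + truth$d1,
    eps = truth$a2 * N1 + truth$b2 * N2 + truth$c2 * s2 + truth$d2)
  fit <- fit_coefficients(data)
  for (nm in names(unclass(truth)))
    expect_lt(abs(fit[[nm]] - truth[[nm]]), 1e-8)
})

test_that("fit_coefficients handles degenerate designs", {
  one <- data.frame(N1 = 100, N2 = 10, sigma2 = 5, omega = 3, eps = 40)
  expect_error(fit_coefficients(one[c(1, 1, 1), ]), "at least 4")
  dup <- one[rep(1, 10), ]
  expect_warning(fit <- fit_coefficients(dup), "rank-deficient")
  # minimum-norm solution still reproduces the duplicated row
  expect_equal(fit$a1 * 100 + fit$b1 * 10 + fit$c1 * 5 + fit$d1, 3,
               tolerance = 1e-8)
  bad <- data.frame(N1 = c(10, 10, 10, 10), N2 = c(20, 0, 0, 0),
                    sigma2 = 1:4, omega = 1:4, eps = 1:4)
  expect_error(fit_coefficients(bad), "exceed")
})
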