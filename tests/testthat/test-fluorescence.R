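test_that("extract_trace sums leaf pixels per frame", {
  mask1 <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2)
  frames <- list(matrix(c(10L, 1L, 1L, 1L), 2), matrix(c(8L, 1L, 1L, 1L), 2),
                 matrix(c(6L, 1L, 1L, 1L), 2))
  tr <- extract_trace(frames, mask1)
  expect_equal(tr$value, c(10, 8, 6))
  expect_equal(tr$kappa_s, c(0, 2, 4))

  mask2 <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2)
  frames2 <- list(matrix(5L, 2, 2), matrix(3L, 2, 2))
  expect_equal(extract_trace(frames2, mask2)$value, c(10, 6))
  expect_equal(extract_trace(frames2, mask2, fun = "mean")$value, c(5, 3))

  expect_error(extract_trace(frames, matrix(FALSE, 2, 2)), "empty leaf mask")
  expect_error(extract_trace(frames[1], mask1), "at least 2 frames")
})

test_that("plateau estimation: tail mean and settle time", {
  tr_const <- tibble::tibble(kappa_s = seq(0, 26, 2), value = rep(7, 14))
  pl <- estimate_plateau(tr_const)
  expect_equal(pl$c_plateau, 7)
  expect_equal(pl$kappa_star_s, 0)

  tr <- tibble::tibble(kappa_s = c(0, 2, 4, 6), value = c(20, 12, 10, 10))
  pl2 <- estimate_plateau(tr, tail_frames = 2L)
  expect_equal(pl2$c_plateau, 10)
  expect_equal(pl2$kappa_star_s, 4)

  # planted exponential-to-plateau trace
  k <- seq(0, 26, 2)
  tr3 <- tibble::tibble(kappa_s = k, value = 1000 * (1 + 0.8 * exp(-k / 4)))
  pl3 <- estimate_plateau(tr3)
  expect_lt(abs(pl3$c_plateau - 1000) / 1000, 0.01)

  expect_error(estimate_plateau(tibble::tibble(kappa_s = k, value = rep(-1, 14))),
               "nonpositive plateau")
})

test_that("CF index matches an independent trapezoid oracle", {
  skip_if_not_installed("pracma")
  set.seed(7)
  k <- seq(0, 26, 2)
  for (i in 1:100) {
    cp <- runif(1, 100, 5000)
    vals <- cp * (1 + runif(1, 0, 2) * exp(-k / runif(1, 2, 10))) +
      rnorm(14, 0, cp * 0.01)
    tr <- tibble::tibble(kappa_s = k, value = vals)
    ks <- sample(k[-1], 1)
    keep <- k <= ks
    oracle <- pracma::trapz(k[keep], (vals[keep] - cp) / cp)
    expect_equal(integrate_cf(tr, cp, ks), oracle, tolerance = 1e-12)
  }
})

test_that("CF index is zero on flat traces and scale-invariant", {
  k <- seq(0, 26, 2)
  flat <- tibble::tibble(kappa_s = k, value = rep(500, 14))
  expect_identical(integrate_cf(flat, 500, 26), 0)

  vals <- 2000 * (1 + 0.9 * exp(-k / 5))
  tr <- tibble::tibble(kappa_s = k, value = vals)
  i1 <- integrate_cf(tr, 2000, 26)
  i2 <- integrate_cf(dplyr::mutate(tr, value = value * 37.5), 2000 * 37.5, 26)
  expect_equal(i1, i2, tolerance = 1e-12)
  expect_gt(i1, 0)
})

test_that("CF index grows with decay amplitude and approaches the analytic integral", {
  k <- seq(0, 26, 2)
  idx <- vapply(c(0.2, 0.5, 1, 2), function(b) {
    tr <- tibble::tibble(kappa_s = k, value = 1000 * (1 + b * exp(-k / 5)))
    integrate_cf(tr, 1000, 26)
  }, numeric(1))
  expect_true(all(diff(idx) > 0))

  # trapezoid converges to b*tau*(1 - exp(-kappa*/tau)) as spacing shrinks
  b <- 0.8; tau <- 5
  analytic <- b * tau * (1 - exp(-26 / tau))
  for (n in c(14, 100, 1000)) {
    kk <- seq(0, 26, length.out = n)
    tr <- tibble::tibble(kappa_s = kk, value = 300 * (1 + b * exp(-kk / tau)))
    err <- abs(integrate_cf(tr, 300, 26) - analytic)
    expect_lt(err, 2 * (26 / (n - 1))^2)  # O(h^2) trapezoid error bound
  }
})

test_that("kappa* = 0 with a nonconstant head warns and yields 0", {
  tr <- tibble::tibble(kappa_s = c(0, 2, 4), value = c(10, 5, 5))
  expect_warning(i <- integrate_cf(tr, 5, 0), "nonconstant")
  expect_identical(i, 0)
})
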