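six_times <- seq(4, 24, by = 4)

test_that("noiseless planted cosines are recovered exactly at the 6 x 4-h schedule", {
  t <- six_times
  fit <- cosinor_fit(t, 2 * cos(2 * pi * t / 24 - pi / 2) + 5)
  expect_equal(fit$a, 2, tolerance = 1e-9)
  expect_equal(fit$phi, pi / 2, tolerance = 1e-9)
  expect_equal(fit$mesor, 5, tolerance = 1e-12)
  expect_equal(fit$A, 0.4, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  set.seed(11)
  for (i in 1:20) {
    a <- runif(1, 0.1, 3); phi <- runif(1, 0, 2 * pi)
    mesor <- a + runif(1, 0.5, 5)  # mesor > a
    y <- a * cos(2 * pi * t / 24 - phi) + mesor
    f <- cosinor_fit(t, y)
    expect_equal(f$a, a, tolerance = 1e-9)
    expect_lt(abs(((f$phi - phi + pi) %% (2 * pi)) - pi), 1e-9)
    expect_equal(f$r_squared, 1, tolerance = 1e-9)
  }
})

test_that("closed form agrees with the dense (a, phi) grid search", {
  set.seed(3)
  t <- six_times
  for (i in 1:10) {
    y <- runif(1, 1, 3) * cos(2 * pi * t / 24 - runif(1, 0, 2 * pi)) +
      runif(1, 4, 8) + rnorm(6, 0, 0.3)
    lsq <- cosinor_fit(t, y, method = "lsq")
    grd <- cosinor_fit(t, y, method = "grid", grid_n = 500L)
    expect_equal(grd$a, lsq$a, tolerance = 2e-2)
    expect_lt(abs(((grd$phi - lsq$phi + pi) %% (2 * pi)) - pi), 2 * pi / 400)
    expect_lte(grd$r_squared, lsq$r_squared + 1e-12)  # lsq attains the max R2
  }
})

test_that("constant series is flagged arrhythmic with zero amplitude", {
  fit <- cosinor_fit(six_times, rep(3, 6))
  expect_true(fit$arrhythmic)
  expect_equal(fit$a, 0)
  expect_true(is.na(fit$phi))
  expect_equal(fit$r_squared, 0)
  expect_equal(normalized_amplitude(fit), 0)
})

test_that("adding a constant shifts the mesor only", {
  t <- six_times
  y <- 1.5 * cos(2 * pi * t / 24 - 1) + 6
  f0 <- cosinor_fit(t, y)
  f1 <- cosinor_fit(t, y + 2.5)
  expect_equal(f1$mesor, f0$mesor + 2.5)
  expect_equal(f1$a, f0$a, tolerance = 1e-12)
  expect_equal(f1$phi, f0$phi, tolerance = 1e-12)
})

test_that("phase recovery under noise: median error within 0.15 rad", {
  set.seed(21)
  t <- six_times
  errs <- replicate(500, {
    mesor <- 5; a <- 1.5; phi <- runif(1, 0, 2 * pi)
    y <- a * cos(2 * pi * t / 24 - phi) + mesor + rnorm(6, 0, 0.1 * mesor)
    f <- cosinor_fit(t, y)
    abs(((f$phi - phi + pi) %% (2 * pi)) - pi)
  })
  expect_lte(median(errs), 0.15)
})

test_that("normalized amplitude is scale-invariant", {
  t <- six_times
  y <- 2 * cos(2 * pi * t / 24 - 1.2) + 5
  expect_equal(normalized_amplitude(cosinor_fit(t, y)),
               normalized_amplitude(cosinor_fit(t, 10 * y)), tolerance = 1e-12)
})

test_that("baseline phase is a circular mean", {
  expect_equal(baseline_phase(rep(1.3, 5)), 1.3)
  expect_equal(baseline_phase(c(0.1, 2 * pi - 0.1)), 0, tolerance = 1e-12)
  expect_equal(baseline_phase(c(1, 2), override = 1.70 * pi), 1.70 * pi)
  expect_error(baseline_phase(numeric(0)), "no finite phases")

  set.seed(5)
  phases <- (rnorm(2000, 1.70 * pi, 0.2)) %% (2 * pi)
  expect_equal(baseline_phase(phases), 1.70 * pi, tolerance = 0.02)
})

test_that("phase folding reflects about the baseline and never drops below it", {
  pb <- 1.70 * pi
  expect_equal(fold_phase(pb, pb), pb)
  expect_equal(fold_phase(1.50 * pi, pb), 1.90 * pi)
  for (d in seq(0, pi, by = 0.1)) {
    up <- fold_phase(pb + d, pb)
    dn <- fold_phase(pb - d, pb)
    expect_equal(up, dn)
    expect_gte(up, pb)
  }
})

test_that("fit_rhythms returns one tidy row per seedling", {
  set.seed(9)
  t <- six_times
  dat <- tidyr::expand_grid(id = c("a", "b", "c"), time_h = t) |>
    dplyr::mutate(cf_index = 2 * cos(2 * pi * time_h / 24 - 1.5) + 5 +
                    rnorm(dplyr::n(), 0, 0.05))
  out <- fit_rhythms(dat)
  expect_equal(nrow(out), 3L)
  expect_true(all(c("norm_amplitude", "peak_phase", "folded_phase",
                    "det_coef") %in% names(out)))
  expect_true(all(out$folded_phase >= out$baseline_phase - 1e-12))
})

test_that("cosinor tidiers report the fit", {
  fit <- cosinor_fit(six_times, 2 * cos(2 * pi * six_times / 24 - pi / 2) + 5)
  td <- tidy(fit)
  expect_equal(td$peak_time_h, 6, tolerance = 1e-9)
  gl <- glance(fit)
  expect_equal(gl$nobs, 6L)
  expect_equal(gl$r.squared, 1, tolerance = 1e-9)
})
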