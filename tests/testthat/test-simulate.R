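test_that("population simulation is deterministic and self-consistent", {
  p <- tiny_params()
  t1 <- simulate_population(p, seed = 4)
  t2 <- simulate_population(p, seed = 4)
  expect_identical(t1, t2)
  expect_false(identical(t1, simulate_population(p, seed = 5)))

  # planted index equals mesor * (1 + A cos(...)) at every time
  for (t in p$times_h) {
    expected <- t1$true_mesor *
      (1 + t1$true_amp * cos(2 * pi * t / 24 - t1$true_phase))
    expect_equal(t1[[paste0("true_cf_", t)]][t1$occupied],
                 expected[t1$occupied], tolerance = 1e-12)
  }
})

test_that("simulated weights look Gaussian and zero-noise weights equal the link", {
  p <- sim_params(n_seedlings = 500L, grid = block_grid(20L, 25L),
                  weight_link = "independent")
  truth <- simulate_population(p, seed = 8)
  w <- truth$weight_g[truth$occupied]
  expect_gt(shapiro.test(w)$p.value, 0.01)

  p0 <- tiny_params(weight_link = "area_linear", weight_noise_sd = 0)
  t0 <- simulate_population(p0, seed = 1)
  area_mean <- rowMeans(t0[, paste0("true_leaf_area_", p0$times_h)])
  expected <- p0$weight_coef$intercept + p0$weight_coef$area * area_mean
  expect_equal(t0$weight_g[t0$occupied], expected[t0$occupied], tolerance = 1e-12)
})

test_that("rendering honors background and blob geometry", {
  p <- tiny_params(bg_sd = 0, leaf_noise_sd = 0, occupancy = 0)
  truth <- simulate_population(p, seed = 2)
  frames <- render_stack(truth, 4, p, seed = 2)
  expect_length(frames, 14L)
  expect_true(all(vapply(frames, function(f) all(f == p$bg_mean), logical(1))))

  p2 <- tiny_params(bg_sd = 0, leaf_noise_sd = 0)
  truth2 <- simulate_population(p2, seed = 2)
  fr <- render_stack(truth2, 4, p2, seed = 2)
  seg <- segment_panel(fr[[1]], p2$grid)
  expect_equal(seg$leaf_area_px, truth2$true_leaf_area_4)
})

test_that("16-bit quantization barely moves the CF index for blobs >= 30 px", {
  p <- tiny_params(bg_sd = 0, leaf_noise_sd = 0, radius_mean_px = 4,
                   radius_sd_px = 0)
  truth <- simulate_population(p, seed = 3)
  fr <- render_stack(truth, 8, p, seed = 3)   # quantized 16-bit render
  seg <- segment_panel(fr[[1]], p$grid)
  for (i in which(truth$occupied)) {
    stopifnot(truth$true_leaf_area_8[i] >= 30)
    b <- cfseedling:::block_bounds(p$grid, truth$row[i], truth$col[i])
    blk <- lapply(fr, function(f) f[b$rows, b$cols])
    mask <- seg$mask[[which(seg$row == truth$row[i] & seg$col == truth$col[i])]]
    r <- cf_index(blk, mask, frame_times_s = p$frame_times_s)
    # same trace without 16-bit rounding, through the same estimators
    n_px <- sum(mask)
    tau <- truth$true_tau_s[i]; bj <- truth$true_b_8[i]
    exact <- tibble::tibble(
      kappa_s = p$frame_times_s,
      value = n_px * p$leaf_plateau_level * (1 + bj * exp(-p$frame_times_s / tau)))
    pl <- estimate_plateau(exact)
    unquantized <- integrate_cf(exact, pl$c_plateau, pl$kappa_star_s)
    expect_lt(abs(r$cf_index - unquantized) / unquantized, 0.005)
  }
})

test_that("unoccupied blocks render as pure sponge and are flagged empty", {
  p <- tiny_params(occupancy = 0.5)
  truth <- simulate_population(p, seed = 10)
  expect_true(any(truth$occupied) && any(!truth$occupied))
  fr <- render_stack(truth, 4, p, seed = 10)
  seg <- segment_panel(fr[[1]], p$grid)
  seg$id <- sprintf("s%02d_%02d", seg$row, seg$col)
  merged <- dplyr::left_join(truth, seg, by = c("id", "row", "col"))
  expect_equal(merged$empty, !merged$occupied)
})
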