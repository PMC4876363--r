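# Ground-truthed synthetic greening panels.
#
# The simulator emulates the factory measurement: a panel of sponge
# blocks, at most one seedling (a bright disc) per block, imaged as a
# 14-frame 16-bit stack per measurement, six measurements 4 h apart
# across one light cycle. Each seedling carries latent circadian
# parameters (normalized amplitude A, peak phase phi, mesor), a decay
# time constant tau, and per-time leaf radii; fresh weight is generated
# from a configurable link. Because the CF index is scale-free, the
# per-measurement decay amplitude b_j is set from the planted index so
# that the planted circadian modulation is exactly recoverable from the
# rendered stacks.

#' Simulation parameters
#'
#' Defaults emulate the factory protocol: 14 frames of 2-s exposure per
#' measurement, 6 measurements every 4 h on the final greening day, a
#' 24-h light period, a 600-block greening panel of 71 x 72-px sponge
#' blocks, and an evening CF peak (phase centered on 1.70 pi rad).
#' Fresh weights come from a linear leaf-area + rhythm-amplitude link
#' calibrated to a roughly Gaussian population around 7 g.
#'
#' @param n_seedlings Number of seedlings (must fit the grid).
#' @param grid A [block_grid()]; default 20 x 30 blocks of 71 x 72 px.
#' @param frame_times_s Frame times within a measurement (seconds).
#' @param times_h Measurement times (hours after lights-on).
#' @param period_h Light period (hours).
#' @param tau_mean_s,tau_sd_s Decay time constant distribution; the trace
#'   converges to its plateau within ~30 s for the default tau ~ 5 s.
#' @param mesor_mean,mesor_sd Mean CF index (seconds) distribution.
#' @param amp_mean,amp_sd Normalized amplitude distribution (truncated
#'   to \[0.02, 0.9\]).
#' @param phase_mean_rad,phase_sd_rad Peak-phase distribution (wrapped).
#' @param bg_mean,bg_sd Sponge background intensity (16-bit counts).
#' @param leaf_plateau_level Per-pixel leaf plateau intensity (counts).
#' @param leaf_noise_sd Per-pixel leaf intensity noise (counts).
#' @param radius_mean_px,radius_sd_px Initial leaf-disc radius.
#' @param growth_frac Fractional radius growth across the measurement day.
#' @param center_jitter_px Uniform jitter of the disc center in the block.
#' @param occupancy Probability a block holds a seedling.
#' @param weight_link `"area_amplitude"` (default), `"area_linear"`,
#'   `"cf_threshold"` or `"independent"`.
#' @param weight_coef Named list of link coefficients
#'   (`intercept`, `area` per pixel, `amp`, `cf_slope`, `cf_thresh`).
#' @param weight_noise_sd Gaussian weight noise (grams).
#' @param weight_mean_g,weight_sd_g Population mean/SD used by the
#'   `"independent"` link.
#' @return A `cf_sim_params` list.
#' @export
sim_params <- function(n_seedlings = 600L,
                       grid = block_grid(20L, 30L),
                       frame_times_s = seq(0, 26, by = 2),
                       times_h = c(4, 8, 12, 16, 20, 24),
                       period_h = 24,
                       tau_mean_s = 5, tau_sd_s = 0.5,
                       mesor_mean = 5, mesor_sd = 1,
                       amp_mean = 0.3, amp_sd = 0.08,
                       phase_mean_rad = 1.70 * pi, phase_sd_rad = 0.1 * pi,
                       bg_mean = 3000, bg_sd = 300,
                       leaf_plateau_level = 15000, leaf_noise_sd = 200,
                       radius_mean_px = 6, radius_sd_px = 1,
                       growth_frac = 0.3, center_jitter_px = 2,
                       occupancy = 1,
                       weight_link = c("area_amplitude", "area_linear",
                                       "cf_threshold", "independent"),
                       weight_coef = list(intercept = 1.5, area = 0.03,
                                          amp = 4, cf_slope = -0.6,
                                          cf_thresh = 5),
                       weight_noise_sd = 0.5,
                       weight_mean_g = 7, weight_sd_g = 1.5) {
  weight_link <- match.arg(weight_link)
  stopifnot(n_seedlings <= grid$rows * grid$cols,
            all(diff(frame_times_s) > 0), all(diff(times_h) > 0),
            period_h > 0, tau_sd_s >= 0, mesor_sd >= 0, amp_sd >= 0,
            phase_sd_rad >= 0, bg_sd >= 0, leaf_noise_sd >= 0,
            radius_sd_px >= 0, occupancy >= 0, occupancy <= 1,
            weight_noise_sd >= 0)
  structure(as.list(environment()), class = "cf_sim_params")
}

#' @export
print.cf_sim_params <- function(x, ...) {
  cat(sprintf(paste0("<cf_sim_params> %d seedlings on %d x %d blocks; ",
                     "%d frames x %d measurements; link '%s'\n"),
              x$n_seedlings, x$grid$rows, x$grid$cols,
              length(x$frame_times_s), length(x$times_h), x$weight_link))
  invisible(x)
}

rtrunc_norm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  pmin(pmax(rnorm(n, mean, sd), lo), hi)
}

disc_mask <- function(h, w, center_r, center_c, radius) {
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  (rr - center_r)^2 + (cc - center_c)^2 <= radius^2
}

# discrete trapezoid of exp(-kappa/tau) on the frame grid; the planted
# index I(t_j) equals b_j times this factor
decay_integral <- function(frame_times_s, tau_s) {
  y <- exp(-frame_times_s / tau_s)
  sum(diff(frame_times_s) * (head(y, -1) + tail(y, -1)) / 2)
}

link_weight <- function(truth, params) {
  cf_mean <- rowMeans(truth[, paste0("true_cf_", params$times_h)])
  area_mean <- rowMeans(truth[, paste0("true_leaf_area_", params$times_h)])
  co <- params$weight_coef
  base <- switch(params$weight_link,
    area_amplitude = co$intercept + co$area * area_mean + co$amp * truth$true_amp,
    area_linear    = co$intercept + co$area * area_mean,
    cf_threshold   = co$intercept + co$area * area_mean +
      co$cf_slope * pmax(cf_mean - co$cf_thresh, 0),
    independent    = rep(params$weight_mean_g, nrow(truth))
  )
  noise_sd <- if (params$weight_link == "independent") {
    params$weight_sd_g
  } else {
    params$weight_noise_sd
  }
  pmax(base + rnorm(nrow(truth), 0, noise_sd), 0.1)
}

#' Simulate a ground-truthed seedling population
#'
#' Draws per-seedling latent parameters and derives every quantity the
#' pipeline is supposed to recover: per-time leaf areas (discrete disc
#' pixel counts at the jittered center actually rendered), planted CF
#' indices `I(t_j) = mesor * (1 + A cos(2 pi t_j / T - phi))`, planted
#' plateaus, per-measurement decay amplitudes, and fresh weight from the
#' configured link.
#'
#' @param params A [sim_params()] object.
#' @param seed RNG seed.
#' @return A tibble, one row per grid block, with `id`, `row`, `col`,
#'   `occupied`, latent parameters (`true_tau_s`, `true_mesor`,
#'   `true_amp`, `true_phase`, disc geometry), per-time
#'   `true_leaf_area_*`, `true_cf_*`, `true_plateau_*`, `true_b_*`
#'   columns, and `weight_g`.
#' @export
simulate_population <- function(params = sim_params(), seed = 1L) {
  stopifnot(inherits(params, "cf_sim_params"))
  g <- params$grid
  n_blocks <- g$rows * g$cols
  withr::with_seed(seed, {
    cells <- tidyr::expand_grid(row = seq_len(g$rows), col = seq_len(g$cols))
    occupied <- rep(FALSE, n_blocks)
    occupied[seq_len(params$n_seedlings)] <- runif(params$n_seedlings) <= params$occupancy
    truth <- cells |>
      dplyr::mutate(
        id = sprintf("s%02d_%02d", .data$row, .data$col),
        occupied = occupied,
        true_tau_s = rtrunc_norm(n_blocks, params$tau_mean_s, params$tau_sd_s, lo = 1),
        true_mesor = rtrunc_norm(n_blocks, params$mesor_mean, params$mesor_sd, lo = 0.5),
        true_amp = rtrunc_norm(n_blocks, params$amp_mean, params$amp_sd, 0.02, 0.9),
        true_phase = (rnorm(n_blocks, params$phase_mean_rad,
                            params$phase_sd_rad)) %% (2 * pi),
        radius0_px = rtrunc_norm(n_blocks, params$radius_mean_px,
                                 params$radius_sd_px, lo = 2),
        center_r = (g$block_height_px + 1) / 2 +
          runif(n_blocks, -params$center_jitter_px, params$center_jitter_px),
        center_c = (g$block_width_px + 1) / 2 +
          runif(n_blocks, -params$center_jitter_px, params$center_jitter_px)
      ) |>
      dplyr::relocate("id")

    t1 <- params$times_h[1]
    tn <- params$times_h[length(params$times_h)]
    for (t in params$times_h) {
      r_t <- truth$radius0_px * (1 + params$growth_frac * (t - t1) / (tn - t1))
      area <- purrr::pmap_int(
        list(truth$center_r, truth$center_c, r_t),
        function(cr, cc, r) sum(disc_mask(g$block_height_px, g$block_width_px,
                                          cr, cc, r)))
      cf <- truth$true_mesor *
        (1 + truth$true_amp * cos(2 * pi * t / params$period_h - truth$true_phase))
      dint <- vapply(truth$true_tau_s, decay_integral,
                     numeric(1), frame_times_s = params$frame_times_s)
      truth[[paste0("radius_px_", t)]] <- r_t
      truth[[paste0("true_leaf_area_", t)]] <- ifelse(truth$occupied, area, 0L)
      truth[[paste0("true_cf_", t)]] <- ifelse(truth$occupied, cf, NA_real_)
      truth[[paste0("true_b_", t)]] <- ifelse(truth$occupied, cf / dint, NA_real_)
      truth[[paste0("true_plateau_", t)]] <-
        ifelse(truth$occupied, area * params$leaf_plateau_level, NA_real_)
    }
    truth$weight_g <- ifelse(truth$occupied, link_weight(truth, params), NA_real_)
  })
  truth
}

#' Render one measurement's panel image stack
#'
#' Builds the 14-frame 16-bit image stack of the whole panel at
#' measurement time `time_h`. Sponge background pixels are Gaussian;
#' leaf-disc pixels follow the exponential-to-plateau decay
#' `level * (1 + b_j exp(-kappa/tau))` with `b_j` taken from the ground
#' truth so that the plateau-normalized index of the rendered trace
#' matches the planted `I(t_j)`. Intensities are rounded to integer
#' counts and clipped to the 16-bit range (with a warning on overflow).
#'
#' @param truth Population tibble from [simulate_population()].
#' @param time_h One of the measurement times in `params$times_h`.
#' @param params The [sim_params()] used to generate `truth`.
#' @param seed RNG seed for the rendering noise.
#' @return List of integer matrices, one per frame.
#' @export
render_stack <- function(truth, time_h, params, seed = 1L) {
  stopifnot(time_h %in% params$times_h)
  g <- params$grid
  H <- g$rows * g$block_height_px
  W <- g$cols * g$block_width_px
  n_frames <- length(params$frame_times_s)
  withr::with_seed(seed + round(1000 * time_h), {
    frames <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      frames[[f]] <- matrix(rnorm(H * W, params$bg_mean, params$bg_sd), H, W)
    }
    for (i in seq_len(nrow(truth))) {
      if (!truth$occupied[i]) next
      b <- block_bounds(g, truth$row[i], truth$col[i])
      mask <- disc_mask(g$block_height_px, g$block_width_px,
                        truth$center_r[i], truth$center_c[i],
                        truth[[paste0("radius_px_", time_h)]][i])
      if (!any(mask)) next
      n_px <- sum(mask)
      b_j <- truth[[paste0("true_b_", time_h)]][i]
      tau <- truth$true_tau_s[i]
      for (f in seq_len(n_frames)) {
        level <- params$leaf_plateau_level *
          (1 + b_j * exp(-params$frame_times_s[f] / tau))
        blk <- frames[[f]][b$rows, b$cols]
        blk[mask] <- level + rnorm(n_px, 0, params$leaf_noise_sd)
        frames[[f]][b$rows, b$cols] <- blk
      }
    }
  })
  over <- FALSE
  frames <- lapply(frames, function(fr) {
    q <- round(fr)
    if (any(q > 65535)) over <<- TRUE
    matrix(as.integer(pmin(pmax(q, 0), 65535)), nrow(fr), ncol(fr))
  })
  if (over) warning("rendered intensities clipped to the 16-bit range")
  frames
}

#' Simulate and write a full measurement-day dataset
#'
#' Renders one stack per measurement time and writes the same artifact
#' layout the pipeline reads: `stack_t<NN>h.tif` multi-page 16-bit TIFFs,
#' `layout.yaml` (grid + schedules), and `ground_truth.csv`.
#'
#' @param params A [sim_params()].
#' @param dir Output directory (created if missing).
#' @param seed Master seed (population and rendering noise both derive
#'   from it).
#' @return Invisibly, the ground-truth tibble.
#' @export
simulate_panel_dataset <- function(params = sim_params(), dir, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  truth <- simulate_population(params, seed = seed)
  for (t in params$times_h) {
    frames <- render_stack(truth, t, params, seed = seed)
    write_stack(frames, file.path(dir, sprintf("stack_t%02dh.tif", t)))
  }
  write_layout(params, file.path(dir, "layout.yaml"))
  truth_flat <- dplyr::select(truth, !dplyr::where(is.list))
  readr::write_csv(truth_flat, file.path(dir, "ground_truth.csv"))
  invisible(truth)
}

#' Ground truth as a per-seedling record table
#'
#' Maps a [simulate_population()] tibble onto the record-table layout
#' [pipeline_records()] produces (leaf areas, CF indices, rhythm
#' features, weight), using the planted values directly. This gives
#' noise-free "perfect pipeline" records for testing the feature
#' assembly and prediction protocol in isolation from image rendering.
#'
#' @param truth Tibble from [simulate_population()].
#' @param params The matching [sim_params()].
#' @return Record tibble of the occupied blocks.
#' @export
truth_records <- function(truth, params) {
  occ <- dplyr::filter(truth, .data$occupied)
  out <- tibble::tibble(id = occ$id, row = occ$row, col = occ$col)
  for (t in params$times_h) {
    out[[paste0("leaf_area_", t)]] <- occ[[paste0("true_leaf_area_", t)]]
    out[[paste0("cf_", t)]] <- occ[[paste0("true_cf_", t)]]
  }
  pb <- baseline_phase(occ$true_phase)
  out$amplitude <- occ$true_amp * occ$true_mesor
  out$norm_amplitude <- occ$true_amp
  out$peak_phase <- occ$true_phase
  out$folded_phase <- fold_phase(occ$true_phase, pb)
  out$mean_cf <- occ$true_mesor
  out$det_coef <- 1
  out$arrhythmic <- FALSE
  out$weight_g <- occ$weight_g
  out
}
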