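# The full diagnosis pipeline: stacks -> segmentation -> CF indices ->
# rhythms -> per-seedling records ready for feature assembly.

#' Process one measurement's panel stack
#'
#' Segments the panel (on the first frame by default — the highest
#' signal, before the decay — or on the per-pixel mean across frames),
#' then extracts each occupied block's decay trace and CF index.
#'
#' @param frames List of frame matrices (from [read_stack()] or
#'   [render_stack()]).
#' @param grid A [block_grid()].
#' @param frame_times_s Frame times (seconds); default 2-s spacing.
#' @param segment_on `"first"` frame (default) or per-pixel `"mean"`.
#' @param min_leaf_area_px,min_separation Occupancy rules, see
#'   [segment_panel()].
#' @param tail_frames,plateau_tol Plateau estimation settings, see
#'   [estimate_plateau()].
#' @return Tibble with one row per block: `row`, `col`, `k_star`,
#'   `leaf_area_px`, `empty`, `c_plateau`, `kappa_star_s`, `cf_index`.
#' @export
process_stack <- function(frames, grid, frame_times_s = NULL,
                          segment_on = c("first", "mean"),
                          min_leaf_area_px = 10L, min_separation = 4,
                          tail_frames = 2L, plateau_tol = 0.02) {
  segment_on <- match.arg(segment_on)
  ref <- if (segment_on == "first") {
    frames[[1]]
  } else {
    r <- Reduce(`+`, lapply(frames, function(f) f / length(frames)))
    matrix(as.integer(round(r)), nrow(r), ncol(r))
  }
  seg <- segment_panel(ref, grid, min_leaf_area_px = min_leaf_area_px,
                       min_separation = min_separation)
  frame_times_s <- frame_times_s %||% (2 * (seq_along(frames) - 1))
  res <- purrr::pmap(seg, function(row, col, k_star, f_max, leaf_area_px,
                                   empty, mask) {
    if (empty) {
      return(tibble::tibble(c_plateau = NA_real_, kappa_star_s = NA_real_,
                            cf_index = NA_real_))
    }
    b <- block_bounds(grid, row, col)
    block_frames <- lapply(frames, function(fr) fr[b$rows, b$cols, drop = FALSE])
    r <- cf_index(block_frames, mask, frame_times_s = frame_times_s,
                  tail_frames = tail_frames, plateau_tol = plateau_tol)
    tibble::tibble(c_plateau = r$c_plateau, kappa_star_s = r$kappa_star_s,
                   cf_index = r$cf_index)
  })
  dplyr::bind_cols(dplyr::select(seg, -"mask"), dplyr::bind_rows(res))
}

#' Build per-seedling records from a measurement day
#'
#' Runs [process_stack()] for every measurement time, keeps blocks
#' occupied at all times, fits the fixed-period cosinor per seedling,
#' and returns the wide record table feature assembly expects:
#' `leaf_area_<t>` and `cf_<t>` per measurement time plus `amplitude`
#' (cosinor `a`), `norm_amplitude` (A), `peak_phase`, `folded_phase`,
#' `mean_cf` (mesor), `det_coef` and `arrhythmic`.
#'
#' @param stacks Named list of frame lists, one per measurement time; the
#'   names are the times in hours (e.g. `"4"`, `"8"`, ...), or supply
#'   `times_h`.
#' @param grid A [block_grid()].
#' @param times_h Measurement times (hours); default parsed from
#'   `names(stacks)`.
#' @param period_h Cosinor period (hours).
#' @param phi_bar Optional fixed baseline phase for folding.
#' @param weights Optional tibble with `id` and `weight_g` to join.
#' @inheritParams process_stack
#' @return Tibble, one row per seedling occupied at every measurement.
#' @export
pipeline_records <- function(stacks, grid, times_h = NULL, period_h = 24,
                             phi_bar = NULL, weights = NULL,
                             frame_times_s = NULL,
                             segment_on = "first", min_leaf_area_px = 10L,
                             min_separation = 4,
                             tail_frames = 2L, plateau_tol = 0.02) {
  times_h <- times_h %||% as.numeric(names(stacks))
  stopifnot(length(times_h) == length(stacks), !anyNA(times_h))
  per_time <- purrr::map2(stacks, times_h, function(frames, t) {
    process_stack(frames, grid, frame_times_s = frame_times_s,
                  segment_on = segment_on,
                  min_leaf_area_px = min_leaf_area_px,
                  min_separation = min_separation,
                  tail_frames = tail_frames, plateau_tol = plateau_tol) |>
      dplyr::mutate(time_h = t)
  }) |>
    dplyr::bind_rows() |>
    dplyr::mutate(id = sprintf("s%02d_%02d", .data$row, .data$col))

  occupied <- per_time |>
    dplyr::summarise(all_occupied = !any(.data$empty),
                     .by = c("id", "row", "col")) |>
    dplyr::filter(.data$all_occupied)

  long <- dplyr::semi_join(per_time, occupied, by = "id")
  wide <- long |>
    dplyr::select("id", "row", "col", "time_h", "leaf_area_px", "cf_index") |>
    tidyr::pivot_wider(names_from = "time_h",
                       values_from = c("leaf_area_px", "cf_index"),
                       names_glue = "{.value}_{time_h}") |>
    dplyr::rename_with(~ sub("^leaf_area_px_", "leaf_area_", .x)) |>
    dplyr::rename_with(~ sub("^cf_index_", "cf_", .x))

  rhythms <- fit_rhythms(long, id = id, time_h = time_h, value = cf_index,
                         period_h = period_h, phi_bar = phi_bar) |>
    dplyr::rename(mean_cf = "mesor")

  out <- dplyr::left_join(wide, rhythms, by = "id")
  if (!is.null(weights)) out <- dplyr::left_join(out, weights, by = "id")
  out
}
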