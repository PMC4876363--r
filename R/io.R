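# File formats: 16-bit multi-page TIFF stacks, YAML layout/config,
# CSV tables, JSON run metadata. Times are hours in column names and
# headers, trace times seconds, phases radians, areas pixels.

#' Read a panel image stack
#'
#' Reads a multi-page 16-bit grayscale TIFF into a list of integer
#' matrices. The frame count and bit depth are validated so unit or
#' acquisition errors fail loudly.
#'
#' @param path TIFF file path.
#' @param expect_frames Expected frame count (default 14; `NULL` skips
#'   the check).
#' @return List of integer matrices.
#' @export
read_stack <- function(path, expect_frames = 14L) {
  if (!file.exists(path)) stop("no such stack file: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (!is.null(expect_frames) && length(pages) != expect_frames) {
    stop(sprintf("format error: expected a %d-frame stack, %s has %d frame(s)",
                 expect_frames, basename(path), length(pages)), call. = FALSE)
  }
  bad_depth <- vapply(pages, function(p) max(p) > 65535 || min(p) < 0, logical(1))
  if (any(bad_depth)) {
    stop("format error: expected 16-bit unsigned grayscale frames", call. = FALSE)
  }
  lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]  # tolerate single-channel planar
    matrix(as.integer(p), nrow(p), ncol(p))
  })
}

#' Write a panel image stack
#'
#' @param frames List of integer matrices with values in 0..65535.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(frames, path) {
  stopifnot(is.list(frames), length(frames) >= 1L)
  norm <- lapply(frames, function(fr) {
    if (any(fr < 0 | fr > 65535)) stop("frame values outside 0..65535", call. = FALSE)
    fr / 65535
  })
  tiff::writeTIFF(norm, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Write / read the panel layout file
#'
#' YAML with the block grid and the frame / measurement schedules.
#'
#' @param params A [sim_params()] or a list with `grid`, `frame_times_s`,
#'   `times_h`, `period_h` entries.
#' @param path YAML path.
#' @return `write_layout`: `path` invisibly; `read_layout`: a list with
#'   `grid` (a [block_grid()]), `frame_times_s`, `times_h`, `period_h`.
#' @export
write_layout <- function(params, path) {
  g <- params$grid
  yaml::write_yaml(list(
    grid = list(rows = g$rows, cols = g$cols,
                block_height_px = g$block_height_px,
                block_width_px = g$block_width_px,
                origin_row = g$origin_row, origin_col = g$origin_col),
    frame_times_s = as.numeric(params$frame_times_s),
    times_h = as.numeric(params$times_h),
    period_h = as.numeric(params$period_h)
  ), path)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  if (!file.exists(path)) stop("no such layout file: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  for (f in c("grid", "frame_times_s", "times_h")) {
    if (is.null(y[[f]])) stop("layout schema error: missing field '", f, "'",
                              call. = FALSE)
  }
  for (f in c("rows", "cols", "block_height_px", "block_width_px")) {
    if (is.null(y$grid[[f]])) stop("layout schema error: missing field 'grid.",
                                   f, "'", call. = FALSE)
  }
  list(grid = block_grid(y$grid$rows, y$grid$cols,
                         y$grid$block_height_px, y$grid$block_width_px,
                         y$grid$origin_row %||% 1L, y$grid$origin_col %||% 1L),
       frame_times_s = as.numeric(y$frame_times_s),
       times_h = as.numeric(y$times_h),
       period_h = as.numeric(y$period_h %||% 24))
}

#' Write / read a per-seedling record table
#'
#' CSV with a versioned header comment stating the units (areas in
#' pixels, CF indices in seconds, phases in radians, times in hours).
#'
#' @param records Tibble of per-seedling records.
#' @param path CSV path.
#' @return `write_records`: `path` invisibly; `read_records`: a tibble.
#' @export
write_records <- function(records, path) {
  con <- file(path, "w")
  writeLines(paste("# cfseedling records v1;",
                   "areas px, cf indices s, phases rad, times h"), con)
  close(con)
  readr::write_csv(dplyr::select(records, !dplyr::where(is.list)),
                   path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE)
}

#' Write run metadata
#'
#' JSON sidecar recording seeds, parameter choices and package version,
#' so a run can be reproduced exactly.
#'
#' @param meta Named list.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_run_meta <- function(meta, path) {
  meta$package_version <- as.character(utils::packageVersion("cfseedling"))
  jsonlite::write_json(meta, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
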