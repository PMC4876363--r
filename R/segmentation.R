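# Per-block leaf/sponge segmentation by discriminant-analysis thresholding.
#
# Each sponge block of a greening panel holds at most one seedling. The
# fluorescence intensity histogram of a block is bimodal: a dim sponge
# background mode and a bright leaf mode. The threshold k* maximizes the
# ratio of between-class to within-class variance of the block histogram
# (a discriminant / Otsu-style criterion); pixels strictly above k* are
# leaf, the rest sponge.

#' Intensity histogram of a block
#'
#' Counts pixels at every integer intensity level `0 .. L-1`. One bin per
#' level over the full range — no rebinning — so thresholds are bit-exact
#' reproducible.
#'
#' @param block_pixels Integer (or whole-number numeric) matrix of pixel
#'   intensities.
#' @param L Number of intensity levels. Default `2^16` for 16-bit images.
#' @return Integer vector of length `L`; element `k + 1` counts pixels at
#'   level `k`.
#' @examples
#' h <- block_histogram(matrix(c(1L, 1L, 2L, 3L), 2), L = 8)
#' h
#' @export
block_histogram <- function(block_pixels, L = 2L^16L) {
  px <- as.vector(block_pixels)
  if (anyNA(px)) stop("block_pixels contains NA", call. = FALSE)
  if (any(px < 0) || any(px >= L)) {
    stop("pixel intensities must lie in [0, L)", call. = FALSE)
  }
  tabulate(as.integer(px) + 1L, nbins = as.integer(L))
}

#' Discriminant-analysis threshold of an intensity histogram
#'
#' Finds the threshold `k*` maximizing the separation metric
#' \deqn{f(k) = \frac{n_1(\mu_1-\mu_0)^2 + n_2(\mu_2-\mu_0)^2}
#'                   {n_1\sigma_1^2 + n_2\sigma_2^2}}
#' where class 1 collects intensities strictly below `k` (sponge), class 2
#' intensities at or above `k` (leaf), and \eqn{\mu_0} is the global mean.
#' The scan covers every `k` for which both classes are nonempty.
#'
#' Two delta-function classes give zero within-class variance; such
#' candidates are treated as maximal separation. Ties (including among
#' degenerate candidates) are broken by the smallest `k`.
#'
#' @param hist Integer count vector as returned by [block_histogram()].
#' @return List with `k_star` (threshold level), `f_max` (attained
#'   separation; `Inf` for a perfectly separable histogram).
#' @examples
#' h <- block_histogram(matrix(c(rep(2L, 10), rep(9L, 10)), 4), L = 16)
#' discriminant_threshold(h)
#' @export
discriminant_threshold <- function(hist) {
  n_tot <- sum(hist)
  occupied <- which(hist > 0L) - 1L
  if (length(occupied) < 2L) {
    stop("degenerate histogram: fewer than 2 occupied intensity levels",
         call. = FALSE)
  }
  lev <- seq_along(hist) - 1
  h <- as.numeric(hist)
  s0 <- sum(h)
  s1 <- sum(h * lev)
  s2 <- sum(h * lev * lev)
  mu0 <- s1 / s0

  # class 1 = levels < k: cumulative sums up to k-1
  c0 <- cumsum(h)
  c1 <- cumsum(h * lev)
  c2 <- cumsum(h * lev * lev)
  k <- lev[-1]                  # candidate thresholds 1 .. L-1
  n1 <- c0[-length(c0)]
  n2 <- s0 - n1
  valid <- n1 > 0 & n2 > 0
  m1 <- c1[-length(c1)] / n1
  m2 <- (s1 - c1[-length(c1)]) / n2
  v1 <- c2[-length(c2)] / n1 - m1^2
  v2 <- (s2 - c2[-length(c2)]) / n2 - m2^2
  num <- n1 * (m1 - mu0)^2 + n2 * (m2 - mu0)^2
  den <- n1 * pmax(v1, 0) + n2 * pmax(v2, 0)
  f <- ifelse(den > 0, num / den, Inf)
  f[!valid] <- -Inf
  best <- which.max(f)          # ties and Inf runs -> first (smallest k)
  list(k_star = as.integer(k[best]), f_max = f[best])
}

#' Segment one sponge block
#'
#' Applies a threshold: pixels with intensity strictly greater than
#' `k_star` belong to the leaf. A block whose leaf area falls below
#' `min_leaf_area_px` is flagged empty (unoccupied sponge) and excluded
#' from downstream per-seedling analysis.
#'
#' @param block_pixels Integer matrix of pixel intensities.
#' @param k_star Threshold level from [discriminant_threshold()].
#' @param min_leaf_area_px Minimum leaf pixel count for an occupied block.
#' @return List with `mask` (logical matrix), `leaf_area` (pixel count),
#'   `empty` (flag), `k_star`.
#' @export
segment_block <- function(block_pixels, k_star, min_leaf_area_px = 10L) {
  mask <- block_pixels > k_star
  leaf_area <- sum(mask)
  list(mask = mask, leaf_area = as.integer(leaf_area),
       empty = leaf_area < min_leaf_area_px, k_star = as.integer(k_star))
}

#' Panel block grid
#'
#' Geometry of the sponge-block grid over a panel image. The default block
#' size is 71 x 72 pixels (rows x cols of pixels per block).
#'
#' @param rows,cols Number of block rows / columns.
#' @param block_height_px,block_width_px Block size in pixels.
#' @param origin_row,origin_col Top-left pixel offset of the grid (1-based).
#' @return A `cf_grid` list.
#' @export
block_grid <- function(rows, cols, block_height_px = 71L, block_width_px = 72L,
                       origin_row = 1L, origin_col = 1L) {
  stopifnot(rows >= 1, cols >= 1, block_height_px >= 1, block_width_px >= 1,
            origin_row >= 1, origin_col >= 1)
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 block_height_px = as.integer(block_height_px),
                 block_width_px = as.integer(block_width_px),
                 origin_row = as.integer(origin_row),
                 origin_col = as.integer(origin_col)),
            class = "cf_grid")
}

#' @export
print.cf_grid <- function(x, ...) {
  cat(sprintf("<cf_grid> %d x %d blocks of %d x %d px (origin %d,%d)\n",
              x$rows, x$cols, x$block_height_px, x$block_width_px,
              x$origin_row, x$origin_col))
  invisible(x)
}

block_bounds <- function(grid, r, c) {
  r0 <- grid$origin_row + (r - 1L) * grid$block_height_px
  c0 <- grid$origin_col + (c - 1L) * grid$block_width_px
  list(rows = r0:(r0 + grid$block_height_px - 1L),
       cols = c0:(c0 + grid$block_width_px - 1L))
}

#' Segment a whole panel image
#'
#' Cuts the image into sponge blocks per `grid`, computes a
#' discriminant-analysis threshold independently in each block, and
#' segments it. A block is flagged empty (unoccupied sponge) when any of
#' these hold: the histogram is degenerate (a single occupied level, so
#' `k_star = NA`), the leaf area falls below `min_leaf_area_px`, or the
#' attained separation `f_max` falls below `min_separation`. The last
#' rule matters because the discriminant criterion always produces some
#' split: on a unimodal noise-only block the best split of a Gaussian
#' yields `f` below about 2, while a genuine sponge/leaf bimodal
#' histogram separates by orders of magnitude more.
#'
#' @param image Integer matrix (one frame of a panel stack).
#' @param grid A [block_grid()].
#' @param min_leaf_area_px Occupancy cutoff passed to [segment_block()].
#' @param min_separation Minimum `f_max` for an occupied block.
#' @param L Number of intensity levels.
#' @return A tibble with one row per block: `row`, `col`, `k_star`,
#'   `f_max`, `leaf_area_px`, `empty`, and a `mask` list-column of logical
#'   matrices.
#' @examples
#' img <- matrix(100L, 20, 20)
#' img[3:8, 3:8] <- 5000L
#' segment_panel(img, block_grid(2, 2, 10, 10))
#' @export
segment_panel <- function(image, grid, min_leaf_area_px = 10L,
                          min_separation = 4, L = 2L^16L) {
  stopifnot(inherits(grid, "cf_grid"))
  need_r <- grid$origin_row + grid$rows * grid$block_height_px - 1L
  need_c <- grid$origin_col + grid$cols * grid$block_width_px - 1L
  if (need_r > nrow(image) || need_c > ncol(image)) {
    stop(sprintf("grid (%d x %d px needed) does not fit image (%d x %d px)",
                 need_r, need_c, nrow(image), ncol(image)), call. = FALSE)
  }
  cells <- tidyr::expand_grid(row = seq_len(grid$rows), col = seq_len(grid$cols))
  res <- purrr::pmap(cells, function(row, col) {
    b <- block_bounds(grid, row, col)
    px <- image[b$rows, b$cols, drop = FALSE]
    h <- block_histogram(px, L = L)
    if (sum(h > 0L) < 2L) {
      return(tibble::tibble(row = row, col = col, k_star = NA_integer_,
                            f_max = NA_real_, leaf_area_px = 0L, empty = TRUE,
                            mask = list(matrix(FALSE, nrow(px), ncol(px)))))
    }
    th <- discriminant_threshold(h)
    seg <- segment_block(px, th$k_star, min_leaf_area_px)
    empty <- seg$empty || th$f_max < min_separation
    tibble::tibble(row = row, col = col, k_star = seg$k_star,
                   f_max = th$f_max, leaf_area_px = seg$leaf_area,
                   empty = empty, mask = list(seg$mask))
  })
  dplyr::bind_rows(res)
}
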