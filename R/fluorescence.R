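# Per-seedling CF decay traces and the plateau-normalized integrated index.
#
# After the blue excitation LED switches off, chlorophyll fluorescence
# decays over ~30 s to a constant plateau C'. The seedling's CF index for
# one measurement is the time integral of the relative excess
# fluorescence (C(kappa) - C')/C' from excitation-off (kappa = 0) to the
# plateau-reach time kappa*. Normalizing by C' makes the index
# dimensionally a time (seconds) and invariant to optical scale and to
# leaf size, so indices are comparable across seedlings.

#' Extract a seedling's CF decay trace from a frame stack
#'
#' Sums leaf-pixel intensities of each frame over the block's leaf mask.
#' The sum (rather than the mean) is used because the plateau
#' normalization cancels scale and a sum is robust to mask-size
#' differences; set `fun = "mean"` for the per-pixel average.
#'
#' @param frames List of integer matrices (the 14 frames of one block),
#'   or a 3-d array with frames along the third dimension.
#' @param mask Logical matrix, TRUE at leaf pixels.
#' @param frame_times_s Frame acquisition times in seconds from
#'   excitation-light off. Default `0, 2, ..., 2*(n-1)` (2-s exposures
#'   captured back-to-back).
#' @param fun `"sum"` (default) or `"mean"` over leaf pixels.
#' @return A tibble with columns `kappa_s` (frame time) and `value`.
#' @export
extract_trace <- function(frames, mask, frame_times_s = NULL, fun = c("sum", "mean")) {
  fun <- match.arg(fun)
  if (is.array(frames) && length(dim(frames)) == 3L) {
    frames <- lapply(seq_len(dim(frames)[3]), function(f) frames[, , f])
  }
  if (length(frames) < 2L) stop("need at least 2 frames", call. = FALSE)
  if (!any(mask)) stop("empty leaf mask: no seedling in block", call. = FALSE)
  frame_times_s <- frame_times_s %||% (2 * (seq_along(frames) - 1))
  if (length(frame_times_s) != length(frames) || is.unsorted(frame_times_s, strictly = TRUE)) {
    stop("frame_times_s must be strictly increasing, one per frame", call. = FALSE)
  }
  agg <- if (fun == "sum") sum else mean
  vals <- purrr::map_dbl(frames, function(fr) agg(as.numeric(fr[mask])))
  tibble::tibble(kappa_s = as.numeric(frame_times_s), value = vals)
}

#' Estimate the plateau value and plateau-reach time of a decay trace
#'
#' The plateau `C'` is the mean of the last `tail_frames` trace values.
#' The plateau-reach time `kappa*` is the earliest frame time from which
#' every subsequent value stays within `plateau_tol` relative deviation
#' of `C'`; if the trace never settles, the last frame time is used.
#'
#' @param trace Tibble with `kappa_s` and `value` (from [extract_trace()]).
#' @param tail_frames Number of trailing frames averaged for `C'`.
#' @param plateau_tol Relative tolerance defining "settled".
#' @return List with `c_plateau` and `kappa_star_s`.
#' @examples
#' tr <- tibble::tibble(kappa_s = c(0, 2, 4, 6), value = c(20, 12, 10, 10))
#' estimate_plateau(tr)
#' @export
estimate_plateau <- function(trace, tail_frames = 2L, plateau_tol = 0.02) {
  n <- nrow(trace)
  stopifnot(tail_frames >= 1L, tail_frames < n)
  c_plateau <- mean(tail(trace$value, tail_frames))
  if (!is.finite(c_plateau) || c_plateau <= 0) {
    stop("invalid trace: nonpositive plateau", call. = FALSE)
  }
  dev <- abs(trace$value - c_plateau) / c_plateau
  settled <- rev(cumprod(rev(dev <= plateau_tol))) == 1  # TRUE from i to end
  kappa_star <- if (settled[1]) 0 else if (any(settled)) {
    trace$kappa_s[which(settled)[1]]
  } else {
    trace$kappa_s[n]
  }
  list(c_plateau = c_plateau, kappa_star_s = kappa_star)
}

#' Integrated, plateau-normalized CF index
#'
#' Computes \eqn{I = \int_0^{\kappa^*} (C(\kappa) - C')/C' \, d\kappa} by
#' the trapezoid rule on the actual frame-time grid (no interpolation or
#' curve fitting: the trace is 14 discrete samples). Units are seconds.
#' A flat trace gives exactly 0; jointly rescaling the trace and `C'`
#' leaves the index unchanged.
#'
#' @param trace Tibble with `kappa_s` and `value`.
#' @param c_plateau,kappa_star_s Plateau and reach time, typically from
#'   [estimate_plateau()].
#' @return The index `I` (scalar, seconds).
#' @export
integrate_cf <- function(trace, c_plateau, kappa_star_s) {
  if (c_plateau <= 0) stop("c_plateau must be positive", call. = FALSE)
  keep <- trace$kappa_s <= kappa_star_s
  if (sum(keep) < 2L) {
    if (any(trace$value[!keep] != trace$value[1])) {
      warning("kappa* = 0 on a nonconstant trace; index is 0 by definition")
    }
    return(0)
  }
  x <- trace$kappa_s[keep]
  y <- (trace$value[keep] - c_plateau) / c_plateau
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

#' CF index for one block and measurement
#'
#' Convenience wrapper chaining [extract_trace()], [estimate_plateau()]
#' and [integrate_cf()].
#'
#' @inheritParams extract_trace
#' @inheritParams estimate_plateau
#' @return List with `trace`, `c_plateau`, `kappa_star_s`, `cf_index`.
#' @export
cf_index <- function(frames, mask, frame_times_s = NULL, fun = "sum",
                     tail_frames = 2L, plateau_tol = 0.02) {
  tr <- extract_trace(frames, mask, frame_times_s, fun)
  pl <- estimate_plateau(tr, tail_frames, plateau_tol)
  idx <- integrate_cf(tr, pl$c_plateau, pl$kappa_star_s)
  list(trace = tr, c_plateau = pl$c_plateau,
       kappa_star_s = pl$kappa_star_s, cf_index = idx)
}
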