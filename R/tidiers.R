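# broom-style tidiers for fitted objects.

#' Tidy a cosinor fit
#'
#' @param x A `cf_cosinor` object.
#' @param ... Unused.
#' @return One-row tibble: `amplitude`, `mesor`, `norm_amplitude`,
#'   `peak_phase`, `peak_time_h`, `det_coef`, `period_h`, `arrhythmic`.
#' @export
tidy.cf_cosinor <- function(x, ...) {
  tibble::tibble(
    amplitude = x$a, mesor = x$mesor,
    norm_amplitude = if (x$arrhythmic) 0 else x$A,
    peak_phase = x$phi,
    peak_time_h = x$period_h * x$phi / (2 * pi),
    det_coef = x$r_squared, period_h = x$period_h,
    arrhythmic = x$arrhythmic
  )
}

#' Glance at a cosinor fit
#'
#' @inheritParams tidy.cf_cosinor
#' @return One-row tibble with `r.squared`, `nobs`, `period_h`, `method`.
#' @export
glance.cf_cosinor <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, nobs = length(x$values),
                 period_h = x$period_h, method = x$method)
}

#' Tidy a feature-set evaluation
#'
#' @param x A `cf_eval` tibble from [evaluate_feature_sets()].
#' @param ... Unused.
#' @return Tibble without the per-repetition list-column.
#' @export
tidy.cf_eval <- function(x, ...) {
  tibble::as_tibble(x[, setdiff(names(x), "abs_r")])
}

#' Glance at a feature-set evaluation
#'
#' @inheritParams tidy.cf_eval
#' @return One-row tibble: number of sets, best set and its mean |R|,
#'   repetition count and split.
#' @export
glance.cf_eval <- function(x, ...) {
  best <- which.max(x$mean_abs_r)
  tibble::tibble(n_sets = nrow(x), best_set = x$feature_set[best],
                 best_mean_abs_r = x$mean_abs_r[best],
                 reps = x$reps[1], split = x$split[1])
}
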