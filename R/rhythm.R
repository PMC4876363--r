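# Fixed-period cosinor fitting of daily CF indices.
#
# The six CF indices per seedling (one per 4-h measurement) are fitted by
# y(t) = a cos(2 pi t / T - phi) + mesor with the period T fixed to the
# 24-h light cycle and the mesor fixed to the sample mean. For equally
# spaced samples spanning one full period, least squares on the cos/sin
# basis attains the maximum determination coefficient, so the fit is
# closed-form; a dense grid search over (a, phi) is provided as a
# fallback for irregular schedules and as an independent cross-check.

#' Fit a fixed-period cosinor to a CF time series
#'
#' @param times_h Measurement times in hours (t = 0 at greening-light on).
#' @param values CF indices at those times.
#' @param period_h Fixed period in hours (the light cycle; default 24).
#' @param method `"lsq"` (closed-form least squares, default) or
#'   `"grid"` (dense search over amplitude and phase maximizing R^2).
#' @param grid_n Phase/amplitude grid resolution for `method = "grid"`.
#' @return An object of class `cf_cosinor`: amplitude `a`, mesor
#'   (the sample mean), normalized amplitude `A = a / mesor`, peak phase
#'   `phi` in \[0, 2*pi), determination coefficient `r_squared`, period,
#'   the data, and `arrhythmic` flag. A zero-variance series is flagged
#'   arrhythmic with `a = 0`, `phi = NA`, `r_squared = 0`.
#' @examples
#' t <- seq(4, 24, by = 4)
#' fit <- cosinor_fit(t, 2 * cos(2 * pi * t / 24 - pi / 2) + 5)
#' tidy(fit)
#' @export
cosinor_fit <- function(times_h, values, period_h = 24,
                        method = c("lsq", "grid"), grid_n = 400L) {
  method <- match.arg(method)
  stopifnot(length(times_h) == length(values), length(values) >= 3L,
            period_h > 0)
  mesor <- mean(values)
  sst <- sum((values - mesor)^2)
  if (sst == 0) {
    return(new_cf_cosinor(a = 0, mesor = mesor, phi = NA_real_,
                          r_squared = 0, period_h = period_h,
                          times_h = times_h, values = values,
                          arrhythmic = TRUE, method = method))
  }
  w <- 2 * pi * times_h / period_h
  if (method == "lsq") {
    X <- cbind(cos(w), sin(w))
    beta <- stats::lm.fit(X, values - mesor)$coefficients
    a <- sqrt(sum(beta^2))
    phi <- atan2(beta[2], beta[1]) %% (2 * pi)
  } else {
    # exhaustive evaluation of the residual sum of squares on an
    # (a, phi) grid; independent of the closed-form path
    r <- values - mesor
    a_max <- 2 * max(abs(r))
    phis <- seq(0, 2 * pi, length.out = grid_n + 1L)[-(grid_n + 1L)]
    as <- seq(0, a_max, length.out = grid_n)
    best <- list(a = 0, phi = 0, ss = Inf)
    for (p in phis) {
      u <- cos(w - p)
      ss <- sum(r^2) - 2 * as * sum(r * u) + as^2 * sum(u^2)
      i <- which.min(ss)
      if (ss[i] < best$ss) best <- list(a = as[i], phi = p, ss = ss[i])
    }
    a <- best$a; phi <- best$phi
  }
  fitted <- mesor + a * cos(w - phi)
  r2 <- 1 - sum((values - fitted)^2) / sst
  new_cf_cosinor(a = unname(a), mesor = mesor, phi = unname(phi),
                 r_squared = max(0, min(1, r2)), period_h = period_h,
                 times_h = times_h, values = values,
                 arrhythmic = FALSE, method = method)
}

new_cf_cosinor <- function(a, mesor, phi, r_squared, period_h, times_h,
                           values, arrhythmic, method) {
  structure(list(a = a, mesor = mesor,
                 A = if (mesor > 0) a / mesor else NA_real_,
                 phi = phi, r_squared = r_squared, period_h = period_h,
                 times_h = times_h, values = values,
                 arrhythmic = arrhythmic, method = method),
            class = "cf_cosinor")
}

#' @export
print.cf_cosinor <- function(x, ...) {
  cat("<cf_cosinor> period", x$period_h, "h\n")
  if (x$arrhythmic) {
    cat("  arrhythmic (zero-variance series); mesor", format(x$mesor), "\n")
  } else {
    cat(sprintf("  a = %.4g  mesor = %.4g  A = %.4g  phi = %.4g rad (%.3g pi)  R2 = %.4f\n",
                x$a, x$mesor, x$A, x$phi, x$phi / pi, x$r_squared))
  }
  invisible(x)
}

#' Normalized cosinor amplitude
#'
#' The seedling-diagnosis rhythm-strength index `A = a / mesor`
#' (dimensionless; invariant under rescaling all CF indices by a positive
#' constant).
#'
#' @param fit A `cf_cosinor` object.
#' @return `A`.
#' @export
normalized_amplitude <- function(fit) {
  stopifnot(inherits(fit, "cf_cosinor"))
  if (fit$arrhythmic) return(0)
  if (fit$mesor <= 0) stop("mesor <= 0: normalized amplitude undefined",
                           call. = FALSE)
  fit$a / fit$mesor
}

#' Population baseline peak phase
#'
#' Circular mean of a population of peak phases, mapped to \[0, 2*pi).
#' The factory calibration can pin a cultivar constant instead (e.g.
#' 1.70*pi rad for Frillice, 1.66*pi for SB555GL) via `override`.
#'
#' @param phases Numeric vector of peak phases in radians.
#' @param override Optional fixed baseline to use instead of the data.
#' @return Baseline phase in \[0, 2*pi).
#' @export
baseline_phase <- function(phases, override = NULL) {
  if (!is.null(override)) return(override %% (2 * pi))
  phases <- phases[is.finite(phases)]
  if (length(phases) == 0L) stop("no finite phases", call. = FALSE)
  atan2(mean(sin(phases)), mean(cos(phases))) %% (2 * pi)
}

#' Fold a peak phase about a population baseline
#'
#' `phi' = phi_bar + |phi_bar - phi|` reflects phases across the baseline
#' so that the magnitude of deviation from environmental synchrony, not
#' its direction, is the feature. The result is deliberately not
#' re-wrapped and may exceed 2*pi; it is always >= `phi_bar`.
#'
#' @param phi Peak phase(s) in \[0, 2*pi), radians.
#' @param phi_bar Baseline phase in \[0, 2*pi).
#' @return Folded phase(s).
#' @examples
#' fold_phase(1.50 * pi, 1.70 * pi)  # 1.90 pi
#' @export
fold_phase <- function(phi, phi_bar) {
  phi_bar + abs(phi_bar - phi)
}

#' Fit cosinor rhythms for many seedlings
#'
#' Tidy wrapper over [cosinor_fit()]: takes long-format per-measurement
#' CF indices and returns one row per seedling with amplitude, mesor,
#' normalized amplitude, peak phase, folded phase and fit quality.
#' Arrhythmic seedlings get `amplitude = 0`, `det_coef = 0` and a missing
#' phase (imputed downstream during feature assembly).
#'
#' @param data Data frame with one row per (seedling, measurement).
#' @param id,time_h,value Column names (tidy-eval) of the seedling id,
#'   measurement time in hours and CF index.
#' @param period_h Fixed period (hours).
#' @param phi_bar Optional baseline phase; default is the population
#'   circular mean of the fitted phases.
#' @return A tibble with columns `id`, `amplitude`, `mesor`,
#'   `norm_amplitude`, `peak_phase`, `folded_phase`, `det_coef`,
#'   `arrhythmic`.
#' @export
fit_rhythms <- function(data, id = id, time_h = time_h, value = cf_index,
                        period_h = 24, phi_bar = NULL) {
  fits <- data |>
    dplyr::group_by({{ id }}) |>
    dplyr::summarise(fit = list(cosinor_fit(dplyr::pick({{ time_h }})[[1]],
                                            dplyr::pick({{ value }})[[1]],
                                            period_h = period_h)),
                     .groups = "drop") |>
    dplyr::rename(id = 1)
  out <- fits |>
    dplyr::mutate(
      amplitude = purrr::map_dbl(.data$fit, "a"),
      mesor = purrr::map_dbl(.data$fit, "mesor"),
      norm_amplitude = purrr::map_dbl(.data$fit, normalized_amplitude),
      peak_phase = purrr::map_dbl(.data$fit, "phi"),
      det_coef = purrr::map_dbl(.data$fit, "r_squared"),
      arrhythmic = purrr::map_lgl(.data$fit, "arrhythmic")
    ) |>
    dplyr::select(-"fit")
  pb <- baseline_phase(out$peak_phase, override = phi_bar)
  out |>
    dplyr::mutate(folded_phase = ifelse(is.finite(.data$peak_phase),
                                        fold_phase(.data$peak_phase, pb),
                                        NA_real_),
                  baseline_phase = pb) |>
    dplyr::relocate("folded_phase", .after = "peak_phase")
}
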