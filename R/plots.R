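# ggplot2 displays for the main result types.

#' Plot a CF decay trace
#'
#' Decay curve with the plateau level and plateau-reach time marked.
#'
#' @param trace Tibble with `kappa_s`, `value` (see [extract_trace()]).
#' @param c_plateau,kappa_star_s Optional plateau annotations.
#' @return A ggplot.
#' @export
plot_trace <- function(trace, c_plateau = NULL, kappa_star_s = NULL) {
  p <- ggplot2::ggplot(trace, ggplot2::aes(.data$kappa_s, .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "time after excitation off (s)",
                  y = "CF (summed leaf-pixel counts)")
  if (!is.null(c_plateau)) {
    p <- p + ggplot2::geom_hline(yintercept = c_plateau,
                                 linetype = "dashed", colour = "red")
  }
  if (!is.null(kappa_star_s)) {
    p <- p + ggplot2::geom_vline(xintercept = kappa_star_s,
                                 linetype = "dotted", colour = "grey40")
  }
  p
}

#' @export
autoplot.cf_cosinor <- function(object, ...) {
  dat <- tibble::tibble(time_h = object$times_h, cf_index = object$values)
  tt <- seq(min(dat$time_h), max(dat$time_h), length.out = 200)
  yy <- if (object$arrhythmic) rep(object$mesor, length(tt)) else {
    object$mesor + object$a * cos(2 * pi * tt / object$period_h - object$phi)
  }
  ggplot2::ggplot(dat, ggplot2::aes(.data$time_h, .data$cf_index)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(data = tibble::tibble(time_h = tt, cf_index = yy),
                       colour = "steelblue") +
    ggplot2::labs(x = "time after lights-on (h)", y = "CF index I (s)",
                  subtitle = sprintf("A = %.3f, phase = %.2f pi rad, R2 = %.3f",
                                     if (object$arrhythmic) 0 else object$A,
                                     (object$phi %||% NA) / pi,
                                     object$r_squared))
}

#' @export
autoplot.cf_eval <- function(object, ...) {
  dat <- tidy.cf_eval(object)
  dat$feature_set <- factor(dat$feature_set, levels = dat$feature_set)
  ggplot2::ggplot(dat, ggplot2::aes(.data$feature_set, .data$mean_abs_r)) +
    ggplot2::geom_col(fill = "grey70", colour = "grey30") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_abs_r - .data$se_abs_r,
                                        ymax = .data$mean_abs_r + .data$se_abs_r),
                           width = 0.3) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "mean |R| (predicted vs. true weight)") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a panel segmentation
#'
#' Leaf-area map over the block grid; empty blocks are blank.
#'
#' @param seg Tibble from [segment_panel()].
#' @return A ggplot.
#' @export
plot_segmentation <- function(seg) {
  ggplot2::ggplot(seg, ggplot2::aes(.data$col, .data$row,
                                    fill = ifelse(.data$empty, NA,
                                                  .data$leaf_area_px))) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90", name = "leaf area (px)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "block column", y = "block row")
}
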