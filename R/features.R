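# Feature-set assembly and fresh-weight categorization.
#
# Per-seedling records carry 6 leaf areas, 6 CF indices (one per 4-h
# measurement), and 4 rhythm features (normalized amplitude A, peak
# phase phi, mean CF <I>, determination coefficient). The standard
# feature sets range from a single index up to all 16.

measurement_times_h <- function() c(4, 8, 12, 16, 20, 24)

#' Standard feature sets
#'
#' Named column selections over a per-seedling record table:
#' * `leaf_area_1pt` / `cf_1pt` — single measurement at `time_h`;
#' * `amplitude`, `peak_phase`, `mean_cf`, `det_coef` — single rhythm
#'   features (amplitude is the normalized amplitude A);
#' * `leaf_area_2pt` / `cf_2pt` — measurements at 12 and 24 h;
#' * `leaf_area_3pt` / `cf_3pt` — at 8, 16 and 24 h;
#' * `leaf_area_6pt` / `cf_6pt` — all six times;
#' * `rhythm2` = \{A, phi\}; `rhythm3` = rhythm2 + \{mean CF\};
#'   `rhythm4` = rhythm3 + \{determination coefficient\};
#' * `all16` — 6 leaf areas + 6 CF indices + rhythm4 (16 features).
#'
#' @param set Feature-set name.
#' @param time_h Measurement time for the single-point sets (default 24).
#' @return Character vector of record column names, in fixed order.
#' @examples
#' feature_columns("all16")
#' feature_columns("leaf_area_2pt")
#' @export
feature_columns <- function(set, time_h = 24) {
  la <- function(t) paste0("leaf_area_", t)
  cf <- function(t) paste0("cf_", t)
  rhythm <- c("norm_amplitude", "peak_phase", "mean_cf", "det_coef")
  switch(set,
    leaf_area_1pt = la(time_h),
    cf_1pt        = cf(time_h),
    amplitude     = "norm_amplitude",
    peak_phase    = "peak_phase",
    mean_cf       = "mean_cf",
    det_coef      = "det_coef",
    leaf_area_2pt = la(c(12, 24)),
    leaf_area_3pt = la(c(8, 16, 24)),
    leaf_area_6pt = la(measurement_times_h()),
    cf_2pt        = cf(c(12, 24)),
    cf_3pt        = cf(c(8, 16, 24)),
    cf_6pt        = cf(measurement_times_h()),
    rhythm2       = rhythm[1:2],
    rhythm3       = rhythm[1:3],
    rhythm4       = rhythm,
    all16         = c(la(measurement_times_h()), cf(measurement_times_h()), rhythm),
    stop("unknown feature set: ", set, call. = FALSE)
  )
}

#' All standard feature-set names
#' @return Character vector.
#' @export
feature_set_names <- function() {
  c("leaf_area_1pt", "cf_1pt", "amplitude", "peak_phase", "mean_cf",
    "det_coef", "leaf_area_2pt", "leaf_area_3pt", "leaf_area_6pt",
    "cf_2pt", "cf_3pt", "cf_6pt", "rhythm2", "rhythm3", "rhythm4", "all16")
}

#' Assemble a feature matrix for a feature set
#'
#' Selects the set's columns from a per-seedling record table, in the
#' set's fixed order. Arrhythmic seedlings (missing peak phase) are
#' imputed with amplitude 0 and the population baseline phase, and
#' flagged in the `imputed` attribute.
#'
#' Peak phase is a circular quantity: a phase just past 2*pi wraps to
#' near 0 and would enter a regression as a spurious extreme value. The
#' `peak_phase` feature is therefore unwrapped about the population
#' baseline (represented as `phi_bar` plus the signed circular deviation,
#' so all values lie within `phi_bar +/- pi`); seedlings without wrap
#' are unchanged.
#'
#' @param records Per-seedling record data frame (see [pipeline_records()]
#'   or [simulate_population()] for the column layout).
#' @param set Feature-set name, see [feature_columns()].
#' @param time_h Time for single-point sets.
#' @param phi_bar Baseline phase used to impute missing phases; default
#'   the circular mean of the finite phases.
#' @return Numeric matrix, one row per record, with an `imputed` logical
#'   attribute marking imputed rows.
#' @export
assemble_features <- function(records, set, time_h = 24, phi_bar = NULL) {
  cols <- feature_columns(set, time_h)
  missing_cols <- setdiff(cols, names(records))
  if (length(missing_cols)) {
    stop("records lack feature columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  X <- as.matrix(records[, cols, drop = FALSE])
  imputed <- rep(FALSE, nrow(X))
  if ("peak_phase" %in% names(records)) {
    pb <- phi_bar %||% baseline_phase(records$peak_phase)
    if ("peak_phase" %in% cols) {
      phi <- records$peak_phase
      X[, "peak_phase"] <- pb + ((phi - pb + pi) %% (2 * pi)) - pi
    }
    bad <- !is.finite(records$peak_phase)
    if (any(bad)) {
      imputed <- bad
      for (cn in intersect(cols, c("peak_phase"))) X[bad, cn] <- pb
      for (cn in intersect(cols, c("norm_amplitude"))) X[bad, cn] <- 0
    }
  }
  X[!is.finite(X)] <- 0
  attr(X, "imputed") <- imputed
  X
}

#' Categorize fresh weights into four population bands
#'
#' Category 1: `W > mu + sigma`; 2: `mu < W <= mu + sigma`;
#' 3: `mu - sigma < W <= mu`; 4: `W <= mu - sigma` (upper bounds
#' inclusive). Over a Gaussian population the four bands hold about
#' 15.9 / 34.1 / 34.1 / 15.9 percent of plants.
#'
#' @param weight_g Fresh weights (grams).
#' @param mu_w,sigma_w Population mean and SD; default computed from
#'   `weight_g`.
#' @return Integer categories in 1..4.
#' @examples
#' categorize_weight(c(6.5, 5.5, 5.0, 3.9), mu_w = 5, sigma_w = 1)
#' @export
categorize_weight <- function(weight_g, mu_w = mean(weight_g),
                              sigma_w = sd(weight_g)) {
  stopifnot(sigma_w > 0)
  dplyr::case_when(
    weight_g > mu_w + sigma_w ~ 1L,
    weight_g > mu_w           ~ 2L,
    weight_g > mu_w - sigma_w ~ 3L,
    TRUE                      ~ 4L
  )
}

#' Select seedlings for transplanting from predicted weights
#'
#' Flags which seedlings to keep: either every seedling whose predicted
#' weight exceeds an absolute `threshold`, or the top `quota` fraction
#' (ties broken by record order, so the kept count is exact).
#'
#' @param predicted_g Predicted fresh weights.
#' @param rule `"threshold"` or `"quota"`.
#' @param threshold Absolute cutoff (grams) for the threshold rule.
#' @param quota Fraction kept for the quota rule.
#' @return Logical keep flags (TRUE = transplant, FALSE = cull).
#' @export
select_seedlings <- function(predicted_g, rule = c("quota", "threshold"),
                             threshold = NULL, quota = 0.8) {
  rule <- match.arg(rule)
  if (rule == "threshold") {
    stopifnot(!is.null(threshold))
    return(predicted_g > threshold)
  }
  stopifnot(quota > 0, quota <= 1)
  n_keep <- round(quota * length(predicted_g))
  keep <- rep(FALSE, length(predicted_g))
  keep[order(predicted_g, decreasing = TRUE)[seq_len(n_keep)]] <- TRUE
  keep
}
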