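# Repeated neural-network growth-prediction protocol.
#
# For each repetition: a seeded random 70/30 split, z-score
# standardization from the training split, a single-hidden-layer
# feed-forward network trained to regress fresh weight on the feature
# set, and the Pearson correlation R between predicted and true weight
# on the held-out 30%. Mean |R| and its standard error over 40
# repetitions summarize one feature set; sharing the per-repetition
# seeds across feature sets makes comparisons paired.

derive_rep_seeds <- function(master_seed, reps) {
  withr::with_seed(master_seed, sample.int(.Machine$integer.max, reps))
}

#' Train/evaluate a growth-prediction network for one feature set
#'
#' @param records Per-seedling record data frame with a `weight_g` column.
#' @param set Feature-set name ([feature_columns()]).
#' @param split Training fraction (default 0.7).
#' @param reps Number of repetitions (default 40).
#' @param seed Master seed; per-repetition split and network
#'   initialization seeds are derived from it deterministically.
#' @param time_h Time for single-point feature sets.
#' @param hidden Hidden-layer size of the network.
#' @param maxit,decay Training iteration budget and weight decay passed
#'   to [nnet::nnet()].
#' @param restarts Random initializations per repetition; the network
#'   with the lowest training criterion is kept. Guards against poor
#'   local optima of back-propagation training.
#' @param eval_on `"heldout"` (default) computes R on the 30% held-out
#'   seedlings; `"all"` on the full population.
#' @param rep_seeds Optional explicit per-repetition seeds (used by
#'   [evaluate_feature_sets()] for paired comparisons); overrides `seed`.
#' @return A one-row `cf_eval` tibble: `feature_set`, `n_features`,
#'   `mean_abs_r`, `se_abs_r`, `reps`, `reps_used`, `split`, `eval_on`,
#'   and an `abs_r` list-column of the per-repetition values.
#' @export
train_eval_nn <- function(records, set, split = 0.7, reps = 40L, seed = 1L,
                          time_h = 24, hidden = 8L, maxit = 300L,
                          decay = 1e-2, restarts = 3L,
                          eval_on = c("heldout", "all"), rep_seeds = NULL) {
  eval_on <- match.arg(eval_on)
  stopifnot(split > 0, split < 1)
  records <- records[is.finite(records$weight_g), , drop = FALSE]
  n <- nrow(records)
  if (n < 20L) stop("need at least 20 records with weights", call. = FALSE)
  X <- assemble_features(records, set, time_h = time_h)
  w <- records$weight_g
  rep_seeds <- rep_seeds %||% derive_rep_seeds(seed, reps)
  stopifnot(length(rep_seeds) == reps)
  n_train <- round(split * n)

  abs_r <- purrr::map_dbl(rep_seeds, function(s) {
    withr::with_seed(s, {
      idx <- sample.int(n, n_train)
      mu <- colMeans(X[idx, , drop = FALSE])
      sg <- apply(X[idx, , drop = FALSE], 2, sd)
      sg[sg == 0 | !is.finite(sg)] <- 1
      Z <- sweep(sweep(X, 2, mu), 2, sg, "/")
      fits <- lapply(seq_len(restarts), function(r) {
        nnet::nnet(Z[idx, , drop = FALSE], w[idx], size = hidden,
                   linout = TRUE, decay = decay, maxit = maxit,
                   trace = FALSE)
      })
      fit <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
      test <- if (eval_on == "heldout") setdiff(seq_len(n), idx) else seq_len(n)
      pred <- as.numeric(predict(fit, Z[test, , drop = FALSE]))
      if (sd(w[test]) == 0 || sd(pred) == 0) return(NA_real_)
      abs(cor(pred, w[test]))
    })
  })
  used <- is.finite(abs_r)
  if (!all(used)) {
    warning(sum(!used), " repetition(s) skipped (degenerate held-out variance)")
  }
  r <- abs_r[used]
  tibble::tibble(
    feature_set = set, n_features = ncol(X),
    mean_abs_r = mean(r), se_abs_r = sd(r) / sqrt(length(r)),
    reps = as.integer(reps), reps_used = as.integer(sum(used)),
    split = split, eval_on = eval_on, abs_r = list(abs_r)
  ) |>
    structure(class = c("cf_eval", "tbl_df", "tbl", "data.frame"))
}

#' Evaluate several feature sets under a paired repeated-split protocol
#'
#' Runs [train_eval_nn()] for each feature set with identical
#' per-repetition seeds, so each repetition uses the same train/test
#' split across sets and per-repetition |R| values can be compared
#' pairwise.
#'
#' @inheritParams train_eval_nn
#' @param sets Character vector of feature-set names; default all 16
#'   standard sets.
#' @return A `cf_eval` tibble with one row per feature set.
#' @export
evaluate_feature_sets <- function(records, sets = feature_set_names(),
                                  split = 0.7, reps = 40L, seed = 1L,
                                  time_h = 24, hidden = 8L, maxit = 300L,
                                  decay = 1e-2, restarts = 3L,
                                  eval_on = "heldout") {
  rep_seeds <- derive_rep_seeds(seed, reps)
  out <- purrr::map(sets, function(s) {
    train_eval_nn(records, s, split = split, reps = reps, time_h = time_h,
                  hidden = hidden, maxit = maxit, decay = decay,
                  restarts = restarts, eval_on = eval_on,
                  rep_seeds = rep_seeds)
  }) |> dplyr::bind_rows()
  structure(out, class = c("cf_eval", "tbl_df", "tbl", "data.frame"))
}

#' Null quantile of mean |R| for an uninformative predictor
#'
#' Simulates the distribution of the mean of `reps` absolute Pearson
#' correlations between independent Gaussian vectors of length `n_test`,
#' and returns the requested quantile. Used to judge whether a measured
#' mean |R| is distinguishable from chance at the held-out sample size.
#'
#' @param n_test Held-out sample size.
#' @param reps Repetitions averaged per protocol run.
#' @param prob Quantile (default 0.95).
#' @param n_sim Number of simulated protocol runs.
#' @param seed RNG seed.
#' @return The null quantile of mean |R|.
#' @export
null_mean_abs_r <- function(n_test, reps = 40L, prob = 0.95,
                            n_sim = 2000L, seed = 1L) {
  withr::with_seed(seed, {
    sims <- replicate(n_sim, mean(abs(replicate(
      reps, cor(rnorm(n_test), rnorm(n_test))))))
    unname(quantile(sims, prob))
  })
}
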