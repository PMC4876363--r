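make_records <- function(n = 30, seed = 1) {
  p <- sim_params(n_seedlings = n, grid = block_grid(5L, ceiling(n / 5)))
  truth_records(simulate_population(p, seed = seed), p)
}

test_that("feature sets have the documented columns in fixed order", {
  expect_length(feature_columns("all16"), 16L)
  expect_equal(feature_columns("leaf_area_2pt"), c("leaf_area_12", "leaf_area_24"))
  expect_equal(feature_columns("cf_3pt"), c("cf_8", "cf_16", "cf_24"))
  expect_equal(feature_columns("rhythm2"), c("norm_amplitude", "peak_phase"))
  expect_equal(feature_columns("rhythm4"),
               c("norm_amplitude", "peak_phase", "mean_cf", "det_coef"))
  expect_equal(feature_columns("leaf_area_1pt", time_h = 12), "leaf_area_12")
  expect_error(feature_columns("bogus"), "unknown feature set")
  expect_length(feature_set_names(), 16L)
})

test_that("assemble_features builds the matrix and imputes arrhythmic seedlings", {
  rec <- make_records(25)
  X <- assemble_features(rec, "all16")
  expect_equal(dim(X), c(25L, 16L))
  expect_equal(colnames(X), feature_columns("all16"))

  X2 <- assemble_features(rec, "leaf_area_2pt")
  expect_equal(unname(X2[, 1]), rec$leaf_area_12)
  expect_equal(unname(X2[, 2]), rec$leaf_area_24)

  Xa <- assemble_features(rec, "amplitude")
  expect_equal(unname(Xa[, 1]), rec$norm_amplitude)

  rec$peak_phase[3] <- NA_real_
  rec$norm_amplitude[3] <- NA_real_
  Xi <- assemble_features(rec, "rhythm2")
  expect_true(attr(Xi, "imputed")[3])
  expect_equal(unname(Xi[3, "norm_amplitude"]), 0)
  expect_equal(unname(Xi[3, "peak_phase"]),
               baseline_phase(rec$peak_phase))

  expect_error(assemble_features(rec[, 1:4], "all16"), "lack feature columns")
})

test_that("weight categories follow the printed band boundaries", {
  expect_equal(categorize_weight(c(6.5, 5.5, 5.0, 3.9), mu_w = 5, sigma_w = 1),
               c(1L, 2L, 3L, 4L))
  # upper bounds inclusive
  expect_equal(categorize_weight(c(6, 4), mu_w = 5, sigma_w = 1), c(2L, 4L))
})

test_that("category counts over a Gaussian population match the tail fractions", {
  set.seed(123)
  w <- rnorm(20000, 7, 1.5)
  frac <- as.numeric(table(categorize_weight(w, mu_w = 7, sigma_w = 1.5))) / 20000
  expect_equal(frac, c(0.159, 0.341, 0.341, 0.159), tolerance = 0.02)
})

test_that("seedling selection honors quota and threshold rules", {
  set.seed(2)
  pred <- runif(100, 3, 10)
  keep <- select_seedlings(pred, rule = "quota", quota = 0.8)
  expect_equal(sum(keep), 80L)
  expect_true(min(pred[keep]) >= max(pred[!keep]))

  expect_true(all(select_seedlings(pred, rule = "threshold", threshold = 0)))
  expect_equal(sum(select_seedlings(pred, rule = "threshold", threshold = 7)),
               sum(pred > 7))
})

test_that("quota culling enriches for low planted growth potential", {
  set.seed(31)
  # bimodal population: a poor-grower mode and a strong mode
  potential <- c(rnorm(50, 4, 0.5), rnorm(50, 9, 0.5))
  pred <- potential + rnorm(100, 0, 0.8)  # imperfect predictions
  keep <- select_seedlings(pred, rule = "quota", quota = 0.5)
  expect_gt(mean(potential[keep]), mean(potential[!keep]) + 2)
})
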