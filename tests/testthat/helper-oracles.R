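# Independent reference implementations used to cross-check the package.

# Brute-force discriminant threshold: evaluates f(k) directly from the
# pixel values at every candidate level, population variances, no
# cumulative-sum shortcuts.
oracle_threshold <- function(pixels) {
  px <- as.numeric(pixels)
  mu0 <- mean(px)
  ks <- (min(px) + 1):max(px)       # both classes nonempty
  f <- vapply(ks, function(k) {
    c1 <- px[px < k]; c2 <- px[px >= k]
    v1 <- mean((c1 - mean(c1))^2)
    v2 <- mean((c2 - mean(c2))^2)
    num <- length(c1) * (mean(c1) - mu0)^2 + length(c2) * (mean(c2) - mu0)^2
    den <- length(c1) * v1 + length(c2) * v2
    if (den == 0) Inf else num / den
  }, numeric(1))
  list(k_star = ks[which.max(f)], f_max = max(f))
}

# random pixel block with at least two distinct values
random_block <- function(n = 20, lo = 0, hi = 300) {
  repeat {
    px <- sample(lo:hi, n, replace = TRUE)
    if (length(unique(px)) >= 2) return(matrix(px, nrow = 1))
  }
}

# small simulation setup used across tests; any default can be overridden
tiny_params <- function(...) {
  args <- modifyList(list(n_seedlings = 4L, grid = block_grid(2L, 2L, 41L, 42L),
                          radius_mean_px = 5, radius_sd_px = 0.5,
                          center_jitter_px = 1),
                     list(...))
  do.call(sim_params, args)
}
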