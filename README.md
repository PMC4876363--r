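# cfseedling

High-throughput seedling diagnosis from chlorophyll-fluorescence (CF)
image stacks, for plant factories with artificial lighting.

Factories raising thousands of lettuce seedlings per day profit from
identifying and culling predicted poor growers at the greening stage
("seedling diagnosis"). CF imaging supplies the inputs without touching a
plant: after a blue excitation pulse switches off, chlorophyll re-emits
red light that decays over ~30 s to a plateau; imaging a whole greening
panel as a 14-frame stack, 6 times every 4 h across one light cycle,
captures leaf size, CF amount, and the circadian modulation of CF per
seedling. `cfseedling` implements the full computation:

* **Segmentation** — per sponge block, the discriminant-analysis
  (Otsu-style) threshold `k*` maximizing
  `f(k) = [n1(mu1-mu0)^2 + n2(mu2-mu0)^2] / [n1*sigma1^2 + n2*sigma2^2]`
  over one-bin-per-level 16-bit histograms; pixels above `k*` are leaf,
  their count is the leaf area.
* **CF index** — `I = \int_0^{kappa*} (C(kappa) - C')/C' dkappa`
  (trapezoid on the 14-point frame grid), where `C` is the summed
  leaf-pixel trace and `C'` its plateau: a scale-free "amount of CF" in
  seconds.
* **Circadian rhythm** — a fixed-period (24 h) cosinor
  `y(t) = a cos(2*pi*t/T - phi) + <I>` fitted per seedling by closed-form
  least squares on the cos/sin basis; yields amplitude `a`, normalized
  amplitude `A = a/<I>`, peak phase `phi`, folded phase
  `phi' = phi_bar + |phi_bar - phi|` about a population baseline, and the
  determination coefficient.
* **Growth prediction** — the 16 standard feature sets (6 leaf areas,
  6 CF indices, 4 rhythm features, and their documented subsets) feed a
  repeated neural-network protocol: 40 seeded 70/30 splits, z-scoring
  from the training split, an `nnet` regressor of fresh weight, and mean
  |R| +/- SE between predicted and true weight on the held-out 30%,
  paired across feature sets.
* **Synthetic panels** — a ground-truthed simulator renders 16-bit
  multi-page TIFF stacks (sponge background, decaying leaf discs,
  planted circadian modulation, configurable weight links) so every
  stage is testable without factory data.

## Worked example

Simulate a measurement day, run the pipeline, and evaluate feature sets
(a low-measurement-noise population of 150 seedlings, the size of a
weighed factory cohort):

```r
library(cfseedling)
library(dplyr)

# render and process a small panel end to end
p <- sim_params(n_seedlings = 30L, grid = block_grid(5L, 6L))
truth <- simulate_population(p, seed = 42)
stacks <- lapply(setNames(p$times_h, p$times_h),
                 function(t) render_stack(truth, t, p, seed = 42))
rec <- pipeline_records(stacks, p$grid, times_h = p$times_h,
                        weights = select(truth, id, weight_g))
select(rec, id, leaf_area_24, cf_24, norm_amplitude, peak_phase, weight_g)
#> # A tibble: 30 × 6
#>   id     leaf_area_24 cf_24 norm_amplitude peak_phase weight_g
#>   <chr>         <int> <dbl>          <dbl>      <dbl>    <dbl>
#> 1 s01_01          128  6.19          0.344       5.36     6.47
#> 2 s01_02          181  4.66          0.363       5.21     7.47
#> 3 s01_03          272  7.55          0.341       5.30     9.63
#> # …
```

Each row is one seedling: leaf area in pixels at 24 h, the CF index in
seconds, the dimensionless rhythm amplitude, the peak phase in radians
(5.3 rad ~ 1.7 pi: an evening CF peak), and fresh weight in grams.

```r
p2 <- sim_params(n_seedlings = 150L, grid = block_grid(10L, 15L),
                 weight_noise_sd = 0.1)
rec2 <- truth_records(simulate_population(p2, seed = 42), p2)
tab <- evaluate_feature_sets(rec2, c("leaf_area_1pt", "cf_1pt",
                                     "rhythm2", "all16"),
                             reps = 40L, seed = 1L)
tidy(tab)
#> # A tibble: 4 × 8
#>   feature_set   n_features mean_abs_r se_abs_r  reps reps_used split eval_on
#>   <chr>              <int>      <dbl>    <dbl> <int>     <int> <dbl> <chr>
#> 1 leaf_area_1pt          1     0.968   0.00122    40        40   0.7 heldout
#> 2 cf_1pt                 1     0.0759  0.00892    40        40   0.7 heldout
#> 3 rhythm2                2     0.116   0.0142     40        40   0.7 heldout
#> 4 all16                 16     0.987   0.00112    40        40   0.7 heldout
```

Under this population's weight link (leaf area plus rhythm amplitude),
leaf area alone predicts well, rhythm features alone predict little, and
the combined 16-feature set predicts best — mean |R| 0.987 versus 0.968,
a paired improvement over all 40 shared splits. `autoplot(tab)` draws the
mean |R| bar chart with standard errors.

A command-line front end wraps the same functions:

```sh
Rscript inst/scripts/cfseedling run-all --out day1 --seed 1 --n 600 --reps 40
```

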