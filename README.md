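# halospt

Single-particle-tracking mobility statistics and UV-damage survival
analysis for live-cell single-molecule imaging in halophilic archaea.

## What problem this package solves

sptPALM experiments follow individual fluorescently tagged proteins in
living cells. For a DNA-interacting protein, engagement in processes
such as DNA repair shows up as a *mobility slowdown*: trajectories
accumulate longer dwell times on DNA and their jump distances (the
frame-to-frame displacements, JD) shrink. Comparing mobility between
experimental conditions is statistically delicate — track counts and
lengths differ between conditions, the per-track mean jump distance
(MJD) distributions are heavy-tailed mixtures, and plain two-sample
test p-values saturate for datasets of this size.

`halospt` implements the full analysis chain:

* **Tracking**: ThunderSTORM-style localization tables are linked into
  trajectories by exact per-frame bipartite assignment
  (`link_localizations()`), jump distances and weighted MJD (wMJD)
  datasets are computed (`compute_jumps()`, `build_wmjd()`), and
  populations are split at the 250/500 nm JD thresholds
  (`split_populations()`).
* **The normalized-U comparison** (`subsample_compare()`): each
  replicate subsamples both wMJD datasets to `floor(0.6 n)` tracks
  (40% removal), computes the weighted Mann-Whitney U, and folds it to

  ```
  u = min(U_a, U_b) / (n_a * n_b)   in [0, 0.5]
  ```

  where `u = 0.5` means indistinguishable distributions and `u = 0`
  complete separation. The replicate distribution is summarized by
  mean, median and 5%/95% bounds; distributions truncated at 0.5 are
  summarized by a Gaussian fitted to the binned frequencies.
  `control_split()` provides the empirical null by comparing random
  halves of one dataset.
* **UV-damage survival** (`fit_decay()`): the intact-DNA fraction
  after dose `D` follows the Poisson zero-event law
  `exp(-K D)` — lesions accrue independently with mean `K D` — and `K`
  is estimated by nonlinear least squares. `dose_calibration()` maps
  doses to lamp exposure times and back.
* **Ensemble assays**: plate-reader blanking and F/OD kinetics with
  growth-phase segmentation and doubling times, label-mask cell-shape
  descriptors (area, perimeter, aspect ratio, circularity
  `4*pi*area/perimeter^2`), Langmuir monolayer compressibility
  `k = -A (dpi/dA)_T`, phosphate standard curves, FTIR normalization
  and second derivatives, and precision-weighted Gaussian density
  rendering of localizations.
* **Synthetic data** (`simulate_tracks()`, `simulate_plate_reader()`,
  `simulate_cpd_survival()`, `simulate_isotherm()`,
  `simulate_cell_masks()`): generators with known ground truth for
  every input the pipeline consumes, used throughout the test suite.

See the methods vignette (`vignettes/mobility-methods.Rmd`) for the
statistical model, conventions and limitations.

## Worked example

Simulate an untreated and a UV-treated condition (the treatment raises
the slow-state occupancy of a two-state diffusing protein), run the
tracking pipeline and compare mobility:

```r
library(halospt)

masks <- simulate_cell_masks(6, area_um2 = 4, aspect_ratio = 2,
                             pixel_size = 107, seed = 42)
sim_u <- simulate_tracks(track_sim_config(seed = 1), masks$mask,
                         dose = 0, recovery = 0, n_tracks = 1200)
sim_t <- simulate_tracks(track_sim_config(seed = 2), masks$mask,
                         dose = 100, recovery = 180, n_tracks = 1200)

as_wmjd <- function(sim, label) {
  locs <- filter_acquisition(sim$locs, 1000)   # drop bleaching lead-in
  tracks <- link_localizations(locs, max_jump = 800)
  build_wmjd(tracks, label)
}
w_u <- as_wmjd(sim_u, "untreated")
w_t <- as_wmjd(sim_t, "100J_180min")

subsample_compare(w_u, w_t, u_comparison_config(n_replicates = 500,
                                                seed = 7))
#> Subsampled normalized Mann-Whitney U comparison
#>   untreated vs 100J_180min
#>   entries: 918 vs 932 (expanded sizes 7407 vs 7723)
#>   replicates: 500, removal fraction: 0.40
#>   mean u = 0.3618, median = 0.3619, 5%-95% CI [0.3399, 0.3837]

control_split(w_u, u_comparison_config(n_replicates = 500, seed = 7))
#> Subsampled normalized Mann-Whitney U comparison
#>   control split of untreated
#>   entries: 459 vs 459 (expanded sizes 3638 vs 3769)
#>   replicates: 500, removal fraction: 0.40
#>   mean u = 0.4602, median = 0.4610, 5%-95% CI [0.4282, 0.4894]
```

The treated condition separates clearly from the control (mean u 0.36
versus 0.46 for the null split): the simulated slowdown is detected.

The UV side of the pipeline:

```r
sv <- simulate_cpd_survival(survival_sim_config(K_true = 3e-3,
                                                noise_cv = 0.05,
                                                seed = 7))
fit_decay(sv)
#> Exponential CPD survival fit (Poisson zero-event model)
#>   K = 0.003183 m^2/J, I0 = 1  [nls-linear]
#>   RSS = 0.00121 over 6 points

dose_to_exposure(100, dose_calibration(235, 50))
#> [1] 470
```

With 5% band-intensity noise the fitted decay constant lands within a
few percent of the generating `K = 3e-3 m^2/J`; the dose calibration
converts a 100 J/m^2 dose to a 470 ms lamp exposure.

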