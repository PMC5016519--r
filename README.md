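# stormquant

Quantitative analysis of dSTORM single-molecule localization data for
plasma-membrane labeling studies.

A dSTORM reconstruction is a coordinate list — one row per localization of
one fluorophore in one camera frame. Turning that list into biology needs
three corrections that this package implements as a pipeline:

* **Density mapping** — sliding-window localization densities
  (1 µm windows on a 100 nm grid) with robust summaries; exposes
  labeling-efficiency differences and projection artifacts such as two-fold
  membranes, whose median density is 2× a single layer.
* **Blink calibration** — each fluorophore photoswitches and is localized
  ~5 times. On a diluted reference sample (< 20 loc/µm²), localizations are
  grouped into per-fluorophore tracks; the mean track length vs. tracking
  radius saturates, and the saturation level (read at 50 nm) is the
  *conversion factor* (localizations per fluorophore). Aligning tracks of
  length ≥ 3 to their centers of mass and fitting the pooled offsets gives
  the experimental localization precision σₓ, σᵧ. Detected molecular density
  is then `localization density ÷ conversion factor`, e.g. 350 loc/µm² at
  6.7 loc/fluorophore → 52 fluorophores/µm².
* **Spatial statistics** — Ripley's h function

  ```
  K̂(d) = A · Σᵢ Σⱼ k(i,j) / (m·(n−1)),   h(d) = √(K̂(d)/π) − d
  ```

  with a seeded m = 500 test-point subset, k(i,j) = 1 for pair distances
  strictly below d (identical points score 0). h ≡ 0 under complete spatial
  randomness; fluorophore blinking alone produces a peak at ~20–30 nm.
  Observed envelopes (mean ± t-based 95% CI over replicate regions) are
  compared against simulated Poisson (CSR) and Neyman–Scott (blinking) null
  models matched to the measured density.

Seeded generators for all of the above scenes (CSR fields, blinking
fluorophores, double membranes, vesicle projection artifacts) are part of
the package, so every estimator ships with a ground-truth recovery test.

## Worked example

Calibrate on a synthetic diluted reference scene and convert a measured
localization density:

```r
library(stormquant)

reg <- region(0, 5000, 0, 5000)                       # 5 × 5 µm² window
sc  <- simulate_blinking_scene(2, region = reg, seed = 7)
cal <- calibrate_blinking(sc$locs)                    # sweep 1–160 nm
cal
#> <blink_calibration>
#>   conversion factor: 5.66 +/- 0.26 loc/fluorophore (at 50 nm)
#>   precision: sigma_x 9.23 nm, sigma_y 8.68 nm (354 offsets)

molecular_density(350, cal$conversion_factor,
                  density_se = 30, conversion_se = cal$conversion_se)
#>   molecular_density molecular_density_rounded molecular_density_se
#> 1          61.87845                        62             5.998349
```

One scene at 2 fluorophores/µm² yields ~350 tracks, so the factor carries a
~0.26 SE; the generating truth (Poisson-5 blinks conditioned on detection)
has mean 5.03. Dividing a 350 loc/µm² measurement by the calibrated factor
gives ~62 detected fluorophores/µm² with first-order propagated uncertainty.

Density mapping and Ripley analysis of a blink-clustered field:

```r
sam <- simulate_neyman_scott(neyman_scott_params(loc_intensity = 1000),
                             reg, seed = 1)
summarize_density(sliding_window_density(sam$locs, reg))
#>     median     mean      q25      q75 n_windows median_se
#> 1 968.9353 974.4698 916.7325 1031.324      1681  2.966184

grid <- seq(10, 400, 10)
obs <- ripley_envelope(lapply(1:5, function(s) {
  sim <- simulate_neyman_scott(neyman_scott_params(loc_intensity = 1000),
                               reg, seed = s)
  ripley_h(sim$locs, reg, distances = grid, m = 500, seed = s, edge = "guard")
}))
csr <- ripley_envelope(lapply(1:5, function(s) {
  ripley_h(simulate_csr(1000, reg, seed = 100 + s), reg,
           distances = grid, m = 500, seed = s, edge = "guard")
}))
peak_distance(obs, c(10, 100))
#>   d_star h_at_peak at_boundary
#> 1     20      20.9 FALSE

compare_to_nulls(obs, csr)
#> <ripley_comparison>
#>   above csr band for d in [10, 280] nm (28 grid points)
```

The blinking null peaks at 20 nm — the ~2–3σ signature of repeated
localizations at 8 nm precision — and sits significantly above the CSR band
at short distances, which is exactly the excursion a cluster analysis must
discount before claiming biological nano-clusters. `autoplot()` methods and
`plot_ripley_comparison()` draw each of these objects; `run_pipeline()` +
`validate_config()` chain every stage (density → calibration → molecular
density → Ripley vs. nulls) from one seeded YAML config, and a thin CLI over
the same functions lives at `inst/cli/stormquant.R`.

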