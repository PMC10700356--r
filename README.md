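# edgewater

Quantitative image analysis of the leading edge of migrating T cells.

Chemokine-stimulated T cells move by polymerizing actin against the plasma
membrane at the leading edge (LE). Ion influx through the
WNK1–OXSR1/STK39–SLC12A2 pathway, followed by osmotic water entry (largely
via AQP3), is thought to swell the membrane at the LE and open space between
the membrane and the cortical F-actin into which filaments can extend — a
facilitated Brownian ratchet. Testing that mechanism rests on a family of
quantitative readouts from fluorescence microscopy and biochemistry, and
this package implements all of them as composable, tested R functions:

* **Tracking & shape** — triangle auto-thresholding, radius-1 opening,
  8-connected labelling with the inclusive 38–60 µm² particle filter;
  greedy mutual-nearest-neighbour track linking; the assays' exclusion
  rules (dead cells out, tracks shorter than 1/2 — or 1/3 in collagen — of
  the video out); mean speed (path/time) and circularity `4πA/P²`.
* **Polarity profiling** — 12-bin intensity profiles along the cell axis
  (LE-first, anchored by CDC42/CD44), 0–1 normalization,
  25%-of-perimeter polarization ratios, and MPAct/CaaX ratios for
  membrane-proximal F-actin with a front-3/back-3 polarity summary.
* **Membrane-to-F-actin spacing** — straightening of a 30-px band along
  the LE, overlapping 20-px perpendicular line profiles aligned on the
  membrane peak with sub-pixel refinement, and the distance to the highest
  F-actin signal within 400 nm on the interior side
  (`d_spacing = argmax_{0<d≤400nm} I_actin(d)`).
* **Retrograde actin flow** — kymographs along the cortex and a
  Radon-style slope search (shear + projection-variance maximization),
  `v = |slope|·px/dt`.
* **Quantitative chemistry** — z-stack volumetry (Σ slice area · dz),
  Coulter-style modal volume (1-fL bins), medium tonicity design
  (`osm = 292·(1−f)` mOsm/l plus inert-osmolyte supplements), the ICP-MS
  normalization chain (internal standard → blank correction → six-point
  OLS calibration → per-cell), and ²H₂O/dioxane NMR ratios.
* **Statistics** — exact two-sided Mann–Whitney U, tie-corrected
  Kruskal–Wallis, Pearson correlation tests, and the adaptive two-stage
  step-up FDR (stage 1 at α′ = α/(1+α) estimates the true nulls m₀; stage
  2 steps up with thresholds i·α′/m₀), with broom-style `tidy()`/`glance()`
  methods.

Because the original microscopy is not redistributable, the package ships a
**synthetic movie generator** (`generate_cell_movie()` and friends) that
renders polarized two-half-ellipse cells with a cortical actin band at a
configurable membrane spacing (174 nm at the LE, 43 nm at the sides, by
default), rearward-flowing speckles, configurable reporter polarity, dead
cells, z-stacks and ICP-MS plates — all with per-cell ground truth, so every
estimator is validated by parameter recovery.

## Worked example

Simulate an under-agarose-style field, track it, and compare recovered
speeds with the generator's ground truth:

```r
library(edgewater)
library(dplyr)

cfg <- generator_config(image_size_px = c(600, 600), pixel_size_um = 0.325,
                        n_frames = 10, n_cells = 6, speed_um_min = 10,
                        dead_fraction = 0.3, seed = 42)
sim <- generate_cell_movie(cfg, condition = "vehicle")
sim$movie
#> <cell_movie> 10 frame(s) x 4 channel(s) x 600 x 600 px @ 0.3250 um/px, step 15 s
#> channels: membrane, actin, reporter, viability

tracks <- sim$movie |> detect_cells() |> link_tracks() |>
  filter_tracks(n_frames = 10)
track_speeds(tracks, dt_s = 15)
#> # A tibble: 6 × 3
#>   track_id n_frames speed_um_min
#>      <int>    <int>        <dbl>
#> 1        1       10         9.38
#> 2        2       10        10.2
#> 3        3       10        10.3
#> 4        4       10        10.4
#> 5        5       10        10.0
#> 6        6       10         8.86
```

Every recovered speed matches a row of `sim$truth$speed_um_min` (9.38,
10.2, 10.3, 10.4, 10.0, 8.85 µm/min) to within a few percent — the
segmentation, linking and speed definitions are doing what they claim.

The spacing estimator on a synthetic stack of 100 leading-edge line
profiles at SNR 10 recovers the configured 174 nm membrane-to-actin
distance:

```r
stk <- generate_edge_profile_stack(n_lines = 100, true_spacing_nm = 174,
                                   pixel_size_um = 0.0433, snr = 10,
                                   seed = 1)$stack
actin_peak_distance(stk, window_nm = 400)
#> <spacing_result> mean 175.5 nm over 100 lines
```

The tonicity calculator reproduces the experimental dilution series from a
292 mOsm/l isotonic baseline, and the statistics mirror the study's tests:

```r
replace_fraction_osmolarity(292, c(0.05, 0.10, 0.15, 0.20))
#> [1] 277.4 262.8 248.2 233.6

mann_whitney_u(c(9.1, 10.4, 12.2), c(14.8, 15.3, 16.9, 18.2))
#> Mann-Whitney U (exact): statistic = 0, two-sided p = 0.05714 (n = 3, 4)

glance(two_stage_fdr(c(0.001, 0.008, 0.039, 0.041, 0.27, 0.60)))
#> # A tibble: 1 × 4
#>       n discoveries    m0 alpha
#>   <int>       <int> <int> <dbl>
#> 1     6           4     4  0.05
```

Here the two-stage procedure discovers the four smallest p-values: stage 1
rejects two hypotheses at α′ = 0.05/1.05, which lowers the estimated number
of true nulls to m₀ = 4 and lets stage 2 pick up p = 0.039 and 0.041 as
well.

`autoplot()` methods are provided for binned profiles, kymographs and
spacing results, plus `plot_tracks()` and `plot_profile_band()` (mean ±
95% CI across cells).

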