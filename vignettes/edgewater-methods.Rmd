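---
title: "Quantifying the leading edge of migrating T cells: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the leading edge of migrating T cells: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edgewater)
```

# The scientific problem

Chemokine-stimulated T cells migrate by polymerizing branched actin against
the plasma membrane at the leading edge (LE). Ion influx driven by the
WNK1–OXSR1/STK39–SLC12A2 kinase pathway, and the osmotic water entry that
follows it (largely through AQP3), have been proposed to swell the membrane
at the LE, opening space between the membrane and the cortical F-actin into
which filaments can extend — a facilitated Brownian ratchet. Testing that
idea quantitatively requires a family of image-analysis readouts:

* **cell tracking and shape**: migration speed and circularity under
  agarose and in collagen, with the assays' exclusion rules;
* **polarity profiling**: where along the cell axis a fluorescent protein
  sits (12-bin profiles anchored by CDC42/CD44), how concentrated it is
  around the perimeter, and the MPAct/CaaX ratio reporting membrane-proximal
  F-actin;
* **membrane-to-F-actin spacing**: the distance from the plasma-membrane
  peak to the nearest interior F-actin peak along the straightened leading
  edge (hundreds of nanometres at the LE, tens at the sides);
* **retrograde actin flow** from kymographs, a surrogate for polymerization
  rate;
* **volumetry, tonicity design and element/water quantification**: z-stack
  and Coulter-style volumes, media with controlled osmolarity, ICP-MS
  element concentrations and ²H₂O NMR signals;
* **the statistics used on those readouts**: two-sided Mann–Whitney,
  Kruskal–Wallis, Pearson correlation, and the adaptive two-stage step-up
  false-discovery-rate procedure.

This package implements each readout as a composable, tested function, and
pairs them with a synthetic movie generator whose per-cell ground truth
makes every estimator falsifiable end to end.

# The synthetic movie generator

`generator_config()` + `generate_cell_movie()` render four-channel
time-lapse movies (`membrane`, `actin`, `reporter`, `viability`).

**Geometry.** A migrating cell is modelled as two half-ellipses sharing
their minor axis: a blunt front (shorter front semi-axis) and a tapered
rear, matching the extended polarized morphology of migrating T cells.
This keeps area and perimeter analytic: the generator records per-cell
area, circularity (`4πA/P²`), realized speed and direction. Cell areas are
drawn uniformly from 38–60 µm², the window used by the under-agarose
assay's particle filter; aspect ratios are drawn from 1.6–2.2. Dead
(propidium-iodide-positive) cells are round, stationary and bright in the
viability channel.

**Radial intensity model.** All rendered intensity is truncated at the
geometric outline with a half-pixel cosine taper, and the membrane ridge
(a Gaussian of the PSF width) is placed 1.5 σ *inside* the outline. This
choice is deliberate: a triangle threshold on a clean synthetic frame lands
just above the background, so the segmented footprint is the support of the
rendered signal — by construction equal to the analytic outline, which
makes the mask area an honest recovery target rather than a
threshold-dependent quantity. The membrane channel adds an interior fill
(out-of-focus/cytosolic light, as in widefield data of flattened cells) so
masks are filled, not rings.

**Cortical actin.** The actin channel carries a cortical band displaced
*inward from the membrane ridge along the local normal* by the configured
spacing: 174 nm across the front arc (within 60° of the migration
direction, the generator's leading-edge default), 43 nm on the sides, with
a cosine transition over 60–75°. Offsets are applied along the normal
(radial offset divided by the cosine of the radial-to-normal angle) because
the downstream estimator measures normal distances on straightened bands; a
purely radial offset would under-measure by several percent on the curved
flanks. The band is modulated by a frozen 1-D speckle pattern advected
rearward along the band's own arc length at the configured flow rate, so a
kymograph sampled along the cortex shows stripes with exactly that speed.

**Reporter.** The reporter channel is the membrane-channel composition
scaled by an axial factor running linearly from
`reporter_front_enrichment × mpact_front_depletion` at the front tip to 1
at the rear. Because it is proportional to the membrane channel under a
uniform factor, a uniform reporter yields an MPAct/CaaX polarity of exactly
1 — a built-in null.

**Noise and determinism.** Poisson shot noise on the clean signal plus
additive Gaussian read noise, then rounding to integer counts (camera
counts are integral, and integral data round-trip losslessly through
16-bit TIFF). One root seed; each cell draws its parameters from a
counter-derived substream, so increasing `n_cells` never reshuffles
existing cells. Identical config + seed ⇒ bit-identical movies.

**Ground truth for the polarity readouts.** Speed, direction, area,
circularity, spacings and flow are recorded from the drawn parameters. The
MPAct/CaaX polarity and the perimeter polarization, by contrast, are
*pipeline-defined* quantities (they depend on binning and normalization),
so the generator records their realized values computed on the noise-free
first frame with the analytic mask. Recovery tests on noisy frames then
probe rendering, segmentation and profiling — not a tautology, since the
noisy path shares no pixels with the clean one.

**What the generator does not emulate.** No photorealism, 3-D PSF,
deconvolution artefacts, nucleus (beyond what the fill hides), membrane
ruffling, shape change over time, or cell–cell occlusion handling. Passing
recovery tests therefore demonstrates that the estimators are correct and
unbiased under the generator's statistical structure, not that they are
robust to every pathology of real microscopy.

# Tracking and shape

`triangle_threshold()` implements the geometric triangle construction on a
256-bin histogram (peak → far-tail chord, maximal perpendicular distance),
`segment_cells()` follows it with a radius-1 disc binary opening,
8-connected labelling, and the inclusive 38–60 µm² area filter.
Perimeters come from the marching-squares contour resampled to 1 px and
smoothed with a circular 3-point running mean; without smoothing the
staircase inflates perimeters by ~6% and a digitized disc would fail the
circularity ≥ 0.95 benchmark for spurious reasons. The smoothing rounds
true corners slightly, so the π/4 square benchmark is evaluated at a side
length (60 px) where that fixed cost is a small fraction.

`link_tracks()` uses greedy mutual-nearest-neighbour linking (globally
smallest admissible distance first), no gap closing, with the maximum
displacement defaulting to 3× the median per-frame displacement from an
unconstrained first pass. `filter_tracks()` applies the assays' exclusion
rules: viability-positive tracks are removed, and "shorter than half the
video" is a *strict* inequality — a track of exactly half length is kept
(1/3 for the collagen assay). `track_speed()` is path length over elapsed
time (mean speed), not net displacement. The dead-cell call compares the
mask-mean viability intensity against the triangle threshold of that
channel, floored at median + 5 MAD so that a channel containing only noise
cannot produce spurious positives.

# Polarity profiling

`length_profile()` projects mask pixels onto the migration axis through the
mask centroid and averages intensity in 12 equal-length bins spanning the
cell, LE first. Equal *length* (not equal pixel count) was chosen because
the protocol bins the length of a line drawn from LE to TE.
`normalize01()` is the per-protein, per-cell 0–1 normalization used for
fixed-cell profiles, with a degenerate flag for constant profiles.
`anchor_le_te()` orients profiles so the CDC42 peak bin precedes the CD44
peak bin, flagging a conflict when the two markers peak within 2 bins of
each other. `perimeter_polarization()` is the fraction of total perimeter
fluorescence inside the ⌈25%⌉ window centred on the argmax (ties to the
lowest index), which is 0.25 for a uniform contour and 1 for a point
source.

`mpact_polarity()` divides the MPAct profile by the CaaX profile after
normalizing each by its **maximum** (the per-fluorophore normalization used
for ratio imaging); with max-only normalization the shared geometry cancels
and the ratio tracks the true local MPAct/CaaX ratio. Min–max (0–1)
normalization is *not* used here: subtracting per-profile minima puts a
hard zero somewhere mid-cell in both channels and makes mid-cell ratio
bins 0/0. Bins whose normalized CaaX value falls below 0.05 are excluded
as carrying no membrane signal. Polarity is the mean of the front three
ratio bins over the mean of the back three.

# Membrane-to-F-actin spacing

`trace_and_straighten_edge()` selects the contour arc whose outward normal
lies within 60° of the migration direction (the leading edge; a 75–135°
window serves for side measurements), locates the membrane ridge inward of
the support contour, and resamples a 30-px band along the inward normal so
the ridge runs horizontally near row 15. `perpendicular_profiles()` then
averages overlapping 20-px-wide windows of arc positions advanced by 10 px
(50% overlap), 0–1 normalizes each line, and aligns lines on the membrane
peak with 3-point parabolic sub-pixel refinement — sub-pixel matters
because the side spacing (43 nm) is a fraction of even a 43.3 nm pixel.
`actin_peak_distance()` takes, per line, the highest actin sample in the
one-sided interior window (0, 400 nm], refines it with a parabola allowed
to reach one sample beyond its argmax (so a truly coincident peak can
refine back to 0), clamps at 0, and averages over lines. The interior-only
search reflects that cortical actin is intracellular; the window rule is
binding and tested (shrinking the window below the true spacing changes
the answer). `spacing_speed_correlation()`/`pearson_test()` report Pearson
r with a two-sided t test on n − 2 df and the least-squares line.

# Retrograde flow

`build_kymograph()` samples a polyline (resampled to 1-px arc spacing,
bilinear, width-averaged) in every frame. `estimate_flow()` finds the
dominant stripe orientation by Radon-style projection parameterized by
slope: the kymograph is sheared so stripes of a candidate slope become
horizontal and the variance of the time-averaged profile is maximized over
a slope grid with parabolic refinement. Three robustness choices matter:
per-column (temporal) means are removed; the static row profile is
subtracted, because structure that never moves is not flow and otherwise
attracts the estimator to zero slope (a kymograph with *no* time-varying
structure at all is reported as zero flow, stationary); and the variance is
computed as a between-row/within-row decomposition over averaging windows
whose length adapts to the candidate slope (~18 px of travel per window),
which keeps fast stripes inside the field of view while leaving scores
comparable across window lengths. `cortical_flow()` wraps the chain for
stationary (PEG-substrate-style) cells: it segments the cell, places the
polyline on one lateral cortical arc moved 2 px inside the contour, and
smooths the polyline so pixelation does not inflate the arc-length scale.
Replacing manual kymograph reading with this automated slope search trades
exact protocol fidelity for reproducibility; recovery on generated movies
is typically within 5% and specified at <10% over 2–10 µm/min, with
occasional ~10% excursions at the fastest flows (the stripe then crosses
the whole arc within a window).

# Volumes, tonicity, ICP-MS and NMR

`stack_volume()` sums z-slice mask areas times the slice spacing (7 slices
at 1 µm by default in the generator). `modal_volume()` is the centre of
the maximal 1-fL histogram bin (ties to the lower bin), the Coulter-counter
modal readout; `median_volume()` is provided because instrument summaries
are sometimes reported as medians — the modal form is the default
aggregator. The mode of a histogram is unstable below ~100 cells, so
`modal_volume()` refuses smaller samples; at the generator's defaults
(mode 60 fL, SD 5 fL, n = 2000) the histogram mode lands within 2 fL of
the true mode.

Tonicity arithmetic is linear in concentration (ideal, dilute solutions;
1 mM of a non-ionic osmolyte contributes 1 mOsm/l):
`replace_fraction_osmolarity(292, f) = 292·(1 − f)` reproduces the
experimental series 277.4 / 262.8 / 248.2 / 233.6 mOsm/l exactly,
`percent_tonicity_reduction(292, 248)` rounds to the ~15% working
reduction, and `isotonic_supplement()` returns the d-sorbitol/L-glucose mM
needed to restore a target osmolarity.

`icpms_calibration()`/`icpms_concentration()` implement the instrument
normalization chain in order: internal-standard (Ga/Ce) division, blank
correction by the mean normalized repeat-blank signal, external
standardization against an ordinary-least-squares six-point calibration
line (free intercept), then per-cell normalization. Negative
blank-corrected signals are clamped to zero with a flag rather than
propagated. At zero noise the chain inverts `generate_icpms_batch()`
exactly. `fold_vs_control()` and `nmr_water_signal()` are the cross-site
and ²H₂O/dioxane normalizations.

# Statistics

`mann_whitney_u()` reports the exact two-sided p (from the symmetric null
distribution of U) when the smaller group has ≤ 8 observations and there
are no ties, and a tie-corrected, continuity-corrected normal approximation
otherwise. `kruskal_wallis()` computes H with tie correction against the
χ² reference. Both are cross-checked in the tests against enumeration
oracles and base R.

`two_stage_fdr()` implements the adaptive two-stage linear step-up
procedure: stage 1 runs the Benjamini–Hochberg step-up at
α′ = α/(1+α); its rejection count r₁ estimates the true nulls as
m₀ = m − r₁; stage 2 re-runs the step-up with thresholds i·α′/m₀ (nothing
is rejected if r₁ = 0, everything if r₁ = m). This is the published
two-stage definition, which uses the corrected level α′ in *both* stages —
a consequence worth stating: for very small r₁ the procedure can reject
marginally fewer hypotheses than plain BH at α, so "never fewer than BH"
is not an invariant of the method and is not asserted. q-values are the
adaptive step-up q-values scaled so that `q ≤ α` reproduces the stage-2
discovery set exactly; like the procedure, they depend on the chosen α.
Monotonicity in p is enforced. One-/two-way ANOVA, mixed-effects and
Friedman analyses are routine fits delegated to base R (`aov`,
`friedman.test`) or `lme4`/`nlme` and are not re-implemented here.

# Numerical choices and degenerate inputs

* Coordinates are pixel-centred; physical positions in µm; all distances
  reported in physical units (nm for spacings).
* Sub-pixel peak localization is a 3-point parabola throughout; within the
  actin window it may reach one sample past its argmax and distances clamp
  at 0 (coincident peaks).
* Constant images have no triangle threshold (error); constant profiles
  0–1-normalize to zeros with a degenerate flag; empty masks, empty groups,
  zero internal standards and non-positive control means are errors, not
  NaNs.
* Movie TIFFs are written 16-bit when the data are integral counts
  (lossless round trip) and 32-bit float otherwise; acquisition metadata
  travels in a JSON side-car because the available TIFF writer cannot embed
  an image description, and reading a movie without pixel-size metadata is
  an error unless an override is supplied.

# Problem sizes used in the tests

The test suite and acceptance analyses run the generator at deliberately
modest sizes — tracking fields of 400–1000 px at 0.325 µm/px with 5–10
cells and 8–12 frames, single-cell super-resolution-like frames of 480 px
at 0.0433 µm/px, 60-frame speckle-flow movies, 100-line profile stacks,
2000-cell volume populations, and 1000-replicate null simulations for the
FDR — sizes at which every recovery has comfortable statistical margin
while the whole suite stays fast enough to run on every change.

# Known limitations

* The flow estimator reads a single dominant slope; it does not produce
  spatial flow maps and can be biased when static and moving structure have
  similar contrast after detrending.
* Equivalence with the original interactive toolchain (TrackMate detector
  settings, manual kymograph reading, manual line alignment) is not
  claimed; the automated procedures are validated against generator ground
  truth instead.
* The straightening assumes a convex-ish leading edge arc; deeply ruffled
  edges would need curvature-aware resampling.
* Tonicity arithmetic assumes ideal-solution linearity; it reproduces the
  printed series exactly but does not model activity coefficients.
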