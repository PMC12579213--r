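# cellquant

Quantitative analysis for fluorescence-microscopy studies of Rho GTPase
signalling and cell migration. The package implements, as tested reusable
functions, the bespoke measurements such studies rely on:

* **Condensate-based interaction scoring.** Interacting bait–prey pairs
  form intracellular condensates; per pair the package computes the
  formation **efficiency** (% of co-transfected cells with co-localized
  two-channel condensates), the condensate **SNR** (fraction of a cell's
  integrated fluorescence inside detected condensates), and the
  **protein interaction index** `PI = (efficiency/100) × mean SNR`,
  scaled by the maximum of its normalization scope. Pair scores assemble
  into a GTPase × effector matrix with gene-family reduction (per-family
  maxima), complete-linkage hierarchical clustering on Euclidean
  distances with bootstrap cluster stability, and configurable
  positive-interaction calling.
* **Migration trajectory statistics.** Directionality
  (displacement / total path length), speed (total path length / time),
  turning angles `θ = arccos(a·b/|a||b|)`, six-frame windowed speed and
  direction `(C_{t+3} − C_{t−3})/6`, and directional autocorrelation
  (mean cosine between displacement vectors at increasing lags,
  Δt = 10 min).
* **Boundary localization pipeline.** Cell segmentation (median filter,
  mean-of-positive-pixels threshold, closing, largest component),
  boundary tracing with quadratic-fit inward normals, 5-px membrane
  regions, GFP/iRFP ratio images, the ±45° protrusive wedge partitioned
  into leading edge / arc area / center radial bands (0–10 / 10–50 /
  50–100% of the surface-to-centroid distance), 60 boundary windows,
  signed edge velocity, kymographs, and shape descriptors.
* **Stress fibers.** Detection of fiber-like objects (area 10–150 px,
  aspect ratio > 5), axial orientations in [0°, 180°), and the average
  angle-deviation statistic via the double-angle axial mean.
* **Adhesion puncta.** Focal-adhesion detection by the intensity band
  1200–4500 AU and size band 0.5–15 (area in µm² by default).
* **Recovery kinetics.** Pre-bleach normalization and one-phase
  association fits `F(t) = F0 + (plateau − F0)(1 − e^(−kt))` with
  half-time `ln 2 / k` and mobile/immobile fractions.

A synthetic-data module (`make_condensate_cell()`, `make_population()`,
`make_fiber_image()`, `make_trajectory()`, `make_moving_mask()`,
`make_puncta_image()`, `make_frap_curve()`) generates every input with
recorded, recountable ground truth, so the whole pipeline is testable
without raw microscopy data.

## Worked example

Score a bait–prey pair from a synthetic two-channel condensate image and
a simulated cell population:

```r
library(cellquant)

sim <- make_condensate_cell(n_spots = 6, snr_target = 0.5, seed = 42)
cs1 <- detect_condensates(sim$channel1)
cs2 <- detect_condensates(sim$channel2)
cs1
#> <condensate_set> 6 particles, threshold 10
colocalize(cs1, cs2, max_dist_px = 3)$positive
#> [1] TRUE
compute_snr(sim$channel1, cs1)
#> [1] 0.5

pop <- make_population(n_cells = 200, true_efficiency = 0.3, seed = 42)
pair_score("Rac1", "ROCK1", pop$records)
#> <pair_score> Rac1-ROCK1: efficiency 35.5%, SNR 0.480, PI 0.1706 (n=200)
```

The six condensates co-localize across channels, half of the cell's
integrated fluorescence sits inside them (matching the generator's
target), and 71 of 200 simulated cells were condensate-positive, giving
efficiency 35.5%, mean positive-cell SNR 0.480, and a raw PI of
0.355 × 0.480 ≈ 0.171.

Migration statistics of a persistent random walk (10-min frames, 30°
heading SD), and a FRAP fit:

```r
tr <- make_trajectory(500, step_len_um = 1, turn_sd_deg = 30,
                      dt_min = 10, seed = 42)$trajectory
path_stats(tr)$directionality
#> [1] 0.0899
head(direction_autocorrelation(tr, max_lag_min = 30), 3)
#>   lag_min  mean_cos n_pairs
#> 1       0 1.0000000     500
#> 2      10 0.8606388     499
#> 3      20 0.7503690     498

fr <- make_frap_curve(0.2, 0.8, 0.05, t = 0:200, noise_sd = 0.01, seed = 42)
fit_one_phase(fr$curve)
#> <one_phase_fit> F0=0.1966 plateau=0.7991 k=0.05051 t_half=13.72 mobile=0.750
```

The lag-1 autocorrelation 0.861 sits at the wrapped-normal closed form
`exp(−σ²/2) ≈ 0.872` for σ = 30°, and the fitted rate 0.0505 s⁻¹
recovers the generating k = 0.05 (t½ = ln 2/k ≈ 13.9 s) from a noisy
curve.

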