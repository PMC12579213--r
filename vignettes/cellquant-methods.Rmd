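---
title: "Quantification methods in cellquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantification methods in cellquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellquant)
```

cellquant quantifies the imaging readouts used to dissect Rho GTPase
signalling: how strongly a GTPase binds each candidate effector, how cells
move, where a kinase sits inside a migrating cell, how the actin
cytoskeleton is organized, and how mobile molecules are inside a
condensate. This vignette explains each model, its assumptions and tunable
parameters, the numerical choices made where the procedure was genuinely
open, and what the synthetic-data generators do and do not emulate.

## Condensate-based interaction scoring

In the condensation assay, a bait on a multimerizing scaffold and a prey
on a tetramerizing fluorophore form micron-scale intracellular condensates
only when they interact. Three per-pair statistics summarize an imaging
screen:

* **Efficiency** (0–100%): the percentage of co-transfected cells showing
  co-localized two-channel condensates. Which cells count as
  co-transfected is an explicit boolean per record, because expression
  gating depends on the instrument.
* **SNR** (0–1): per condensate-positive cell, the fraction of the cell
  ROI's integrated fluorescence residing inside detected condensates,
  `sum(particle integrated intensities) / sum(ROI intensities)`.
* **Protein interaction index**: `pi_raw = (efficiency/100) × snr_mean`,
  where `snr_mean` averages only condensate-positive cells (SNR is
  undefined without condensates). Scaled PI divides each entry by the
  maximum of its normalization scope — per effector column by default,
  globally on request; both conventions appear in practice and
  `scale_pi()` exposes both.

Condensates are detected by threshold-then-label particle analysis
(8-connected components, minimum area 4 px to suppress shot noise). The
original workflow tuned each image's threshold by eye, which is not
reproducible; `detect_condensates()` therefore offers `fixed`,
`percentile`, `otsu`, and the default `automatic` policy, a robust
background threshold at median + 3 MAD of the plane. The default is
deliberately *not* Otsu: condensates occupy a small pixel fraction, so the
intensity histogram is dominated by background and Otsu's bisecting
threshold clips the dim Gaussian outskirts of each spot — on generator
fixtures with a known in-spot intensity fraction of 0.5 it recovers
roughly 0.35, while the median + 3 MAD policy tracks the diffuse
background level and recovers the target within 0.05. MAD's 50% breakdown
point keeps the estimate valid as long as condensates cover well under
half the ROI, which holds for any realistic field.

Co-localization across channels is greedy nearest-centroid matching under
a distance cap (default 5 px); one matched pair makes the cell positive.
Positive-interaction calling from a PI matrix uses two configurable
floors (`pi_raw > pi_floor`, `efficiency ≥ eff_floor`, defaults 0 and
10%): screens of this kind report positive counts without publishing an
exact criterion, so the floors are configuration, not constants.

**Matrix operations.** `assemble_pi_matrix()` distinguishes missing pairs
(`NA`) from measured zeros. `family_reduce()` collapses effectors of one
gene family (PAK1–7 → PAK, ROCK1/2 → ROCK, …) by the per-GTPase maximum,
the natural summary when family members share a binding domain.
`cluster_pi()` runs complete-linkage hierarchical clustering on Euclidean
distances for each axis. The number of flat clusters is chosen by ordinary
bootstrap stability — resample the opposite axis with replacement,
recluster, and score each cluster by the fraction of resamples reproducing
its exact member set — rather than multiscale-bootstrap approximately
unbiased p-values, which serve the same decision role at far greater
complexity. Missing entries are imputed as 0 for clustering only (missing
and screen-negative are visually equivalent in a heatmap) and the count of
imputed cells is reported.

## Trajectory statistics

Trajectories are uniformly sampled centroid tracks `C_t = (x_t, y_t)` in
µm. `path_stats()` reports directionality (displacement / total path
length) and speed (total path length / elapsed time; elapsed time, not
frame count, so dropped frames shorten the denominator honestly).
`turning_angle()` is `arccos(a·b / |a||b|)` in degrees with the cosine
clamped to [−1, 1] against floating-point overflow; zero vectors are
rejected, not defaulted. Turn events are supplied by the caller as vector
pairs — automatic retraction/protrusion detection is out of scope.

The six-frame windowed statistics at frame `t` (0-based, valid for
`3 ≤ t ≤ T−3`) are

```
Speed(t)     = Σ_{k=-2..3} |C_{t+k} − C_{t+k−1}| / 6
Direction(t) = Σ_{k=-2..3} (C_{t+k} − C_{t+k−1}) / 6 = (C_{t+3} − C_{t−3}) / 6
```

Out-of-window frames yield no value rather than a truncated sum, since
edge handling is otherwise undefined. The telescoping identity for
Direction is tested exactly.

`direction_autocorrelation()` computes, per lag `L`, the mean cosine
between displacement vectors `C_{t+Δt} − C_t` and `C_{t+L+Δt} − C_{t+L}`
over all overlapping pairs, pooling cells by simple averaging, with
Δt = 10 min by default (finer tracks are resampled by nearest frame).
Zero-length steps are excluded because their direction is undefined. No
lag-0 renormalization is applied beyond the identity value 1.

## The boundary-localization pipeline

The per-frame image algorithm is: median filter → binarize at the mean of
strictly positive filtered pixels → morphological closing (disk, radius
2 px by default) → keep the largest 8-connected object, fill holes. The
mean-of-positive-pixels threshold is applied with `≥` so that a noiseless
uniform object survives its own mean. Segmenting an already-binary mask
reproduces it exactly (idempotence test).

**Boundary normals.** Each boundary pixel's normal comes from a local
quadratic fit over the pixel ± `half_window` contour neighbours,
performed in a chord-aligned frame (abscissa along the chord between the
outermost stencil points) because a fixed `y = f(x)` quadratic is
degenerate at vertical tangents. The default stencil is 7 points
(`half_window = 3`): a 5-point stencil on a digitized circle produces up
to 14° of angular error at the octant boundaries of the pixel grid where
five consecutive boundary pixels form a perfect staircase, whereas 7
points stays under 7° — comfortably inside the 10° accuracy this pipeline
needs for membrane-region geometry. `half_window = 2` remains one
argument away for strict 5-point behaviour. Degenerate stencils fall back
to a chord normal and are flagged.

**Membrane region.** The union of the 5 pixels (configurable) stepped
inward along each boundary normal, clipped to the mask — steps go inward
only, since the outward half would sample background.

**Wedge and radial bands.** The protrusive region is the set of in-mask
pixels whose bearing from the centroid lies within ±45° of the movement
direction (90° total). Each wedge pixel is assigned a band by its
fractional distance from the surface toward the centroid along its own
ray — 0–10% leading edge, 10–50% arc area, 50–100% center. The surface
radius per ray is the outermost mask pixel in that pixel's angular bin
(360 bins); for non-star-shaped masks this is the outermost intersection,
the conservative choice. On a disk the bands occupy 1 − 0.9² = 0.19,
0.9² − 0.5² = 0.56, and 0.5² = 0.25 of the wedge, which the tests check
to ±0.03. Region intensities are reported as plain means of defined
pixels; callers can max-normalize time series as needed.

**Windows and edge velocity.** The contour is split into 60 contiguous
arcs differing by at most one pixel, anchored at the topmost boundary
pixel so windows correspond across frames (rotation-sensitive, by
design — the anchor follows the image frame, not the cell). Edge velocity
per window is the mean change of the signed Euclidean distance field
(positive inside) between consecutive frames, sampled at the window's
boundary pixels, divided by the frame interval: protrusion positive,
retraction negative. This mask-level definition avoids optical flow and
matches a uniform 2 px dilation to within 0.5 px/frame. Front/back
protrusion–retraction summaries compose `edge_velocity()` with
`partition_regions()`; intensity–velocity coupling is a pooled Pearson
correlation over (window, frame) pairs.

**Shape.** Aspect ratio is the axis ratio of the second-moment ellipse
(with a 1/12-pixel variance floor so single-row objects are
non-degenerate); circularity is `4πA/P²` with the perimeter measured as
chain length (diagonal steps √2), which overestimates smooth perimeters
by a few percent — a digital disk scores ≈ 0.92, not 1.

## Stress fibers

Fiber detection median+Gaussian filters (radius/σ 1 px defaults — the
workflow publishes none, and 1 px is the weakest smoothing that still
suppresses single-pixel noise), binarizes (Otsu by default; fibers
occupy enough of their bounding field for a bimodal histogram), labels
8-connected components, and keeps objects with 10 ≤ area ≤ 150 px and
second-moment aspect ratio > 5. Orientation is the ellipse major-axis
angle as an axial quantity in [0, 180).

The average angle deviation is not formula-defined in the source
workflow; cellquant uses the natural axial-statistics reading: the axial
mean via the double-angle transform (angles doubled, vector-averaged,
halved back), and the mean absolute acute axial difference of each fiber
from that mean (≤ 90° by construction). A user-supplied reference axis
(e.g. the cell's polarity axis) can replace the population mean via
`reference_deg`.

## Adhesion puncta

Adhesions are pixels in the 1200–4500 AU intensity band, labelled
8-connected, kept when the per-object mean intensity lies in the band and
the object size lies in 0.5–15. The size unit is ambiguous in the
published criterion (µm vs µm²); the default reads it as area in µm² —
the particle-analysis convention — with an equivalent-circle diameter
mode available. The band is applied twice (pixel threshold, then object
mean) mirroring the threshold-then-measure workflow.

## Recovery kinetics

FRAP-style curves are normalized by the mean of all pre-bleach frames
(30 frames at 1 s spacing in the emulated protocol; a single-frame mode
is a one-argument change) and fitted with the one-phase association

```
F(t) = F0 + (plateau − F0) · (1 − e^(−k t))
```

by Levenberg–Marquardt least squares (`minpack.lm::nlsLM`) with `k`
bounded positive, time measured from the first post-bleach frame, and
`F0` estimated rather than pinned to the first post-bleach sample (robust
to noise at the bleach frame). Starting values come from the data: `F0`
from the early minimum, the plateau from the tail mean, `k` from the time
of ~63% recovery. Derived quantities: `t_half = ln 2 / k`,
`mobile = (plateau − F0)/(pre_level − F0)`, immobile = 1 − mobile. A
model-free half-time interpolates the first crossing of
`(F0 + plateau)/2`; both modes are exposed because published half-times
may come from either. Formation kinetics of rising intensity curves reuse
the same machinery with the stimulus frame as the event index.

## Synthetic data: what it does and does not show

Every generator draws from one explicit stream seeded per call (restored
afterwards; no hidden global state) and records ground truth that can be
recounted from the emitted artifact.

* Condensate cells: isotropic Gaussian spots truncated at 4σ on a uniform
  background; when an SNR target is requested the spot amplitude is
  solved in closed form so the in-ROI intensity fraction equals it.
* Populations: Bernoulli positives at the nominal efficiency; positive
  cells draw SNR from a normal clamped to [0, 1].
* Fibers: anti-aliased rotated rectangles (4×4 supersampling),
  re-binarized at 50% coverage for ground truth, so area and orientation
  are analytically known.
* Trajectories: persistent random walks with wrapped-normal heading
  increments — chosen over von Mises because the lag-1 mean cosine has
  the closed form `exp(−σ²/2)`, an analytic recovery target.
* Mask movies: drifting disks with an optional rotating radial
  protrusion term and painted uniform/wedge intensity fields of known
  contrast.
* Puncta: plateau disks of requested area and intensity; in-band flags
  are judged on the *realized* pixelated object so detector agreement is
  exact, with nominal values recorded alongside.
* Recovery curves: the closed-form association plus Gaussian noise.

None of this emulates a real microscope: there is no PSF, no Poisson/
camera noise model, no 3D, no uneven illumination, no cell-to-cell
texture. Passing tests therefore demonstrate that the estimators
implement their definitions and recover known parameters under idealized
imaging — not that they are robust to every artifact of real data.
Problem sizes used by the test-suite and the acceptance script — 128–400 px
images, 200-cell populations, 5,000-step walks, 200 Monte-Carlo
replicates — were chosen as the smallest sizes at which the analytic
targets are statistically sharp.

## Known limitations

* One cell per ROI; no instance segmentation of dense fields, no
  chromatic registration, no deformable-contour tracking.
* The radial-band partition assumes approximately star-shaped masks;
  strongly concave cells get the outermost-intersection convention.
* Window anchoring is image-frame based and therefore rotation
  sensitive.
* The bootstrap cluster-stability score is not a p-value; it is a
  reproducibility fraction.
* Single-exponential recovery only; reaction–diffusion FRAP models and
  bleach-depth corrections are out of scope.
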