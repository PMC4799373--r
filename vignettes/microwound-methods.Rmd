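---
title: "Quantifying gap closure, migration and tension in wounded 3D microtissues"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying gap closure, migration and tension in wounded 3D microtissues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microwound)
```

## The assay and what the package measures

Engineered microtissues — fibroblasts contracted into a dense collagen band
suspended between two flexible PDMS cantilevers — can be wounded with a
microsurgical knife and imaged every 30 min for 24 h. Three readouts
characterise the repair response:

1. **Gap morphometrics.** The incision leaves a void (the *gap*) enclosed by
   tissue. Its projected area briefly widens, the ragged cut edge smoothens
   into an ellipse, and the area then falls at a constant areal rate
   (on the order of 1,300 µm² h⁻¹) until closure, with the wound centroid
   stationary.
2. **Nuclear migration.** Hoechst-labelled nuclei are tracked; cells at the
   wound edge migrate tangentially along the wound circumference while cells
   ≥ 100 µm away move radially inward. Directionality is summarised as a
   windrose of *radial migration angles* (0° = toward the gap centroid,
   90° = tangential).
3. **Tissue tension.** Fluorescent beads in the cantilever caps report
   cantilever deflection; total tension is the spring constant times the
   summed deflection. After wounding, tension drops sharply, recovers to a
   peak near 10 h, and settles slightly below its pre-wound baseline.

The package implements each stage as a function from calibrated image stacks
(or tables) to tibbles, plus a synthetic scene generator with exact ground
truth so every stage can be validated by parameter recovery.

## Segmentation and gap morphometrics

Frames are segmented by a brightness threshold (per-frame Otsu by default; a
fixed threshold is available when cross-frame reproducibility matters more
than illumination robustness), followed by morphological closing (disc radius
3 px) and removal of components below 50 px. Background components touching
the image border are the space *around* the tissue; enclosed non-tissue
components are holes, and the largest hole is the gap — there is a single
surgical wound per tissue, so ties are broken toward the previous frame's
centroid.

From the gap pixel set we report:

* **area** `A = n · s²` (pixel count times squared pixel size),
* **centroid** (mean pixel position, µm),
* **ellipse** from second central moments: the semi-axes are
  `a, b = 2·sqrt(λ₁), 2·sqrt(λ₂)` for eigenvalues λ of the pixel covariance,
  the convention under which a solid ellipse recovers its own semi-axes;
  orientation is the principal eigenvector angle,
* **circularity** `4πA / P²`, with the perimeter measured by marching squares
  on a lightly smoothed mask (σ = 1.5 px). Contouring the raw binary
  staircase overestimates oblique boundaries by up to ~8%, which alone would
  push a perfect disc's circularity down to ~0.89; after smoothing a
  rasterized disc measures within 0.5% of 1.
* **tissue width**: the median, over the central half of the occupied span,
  of the tissue extent perpendicular to the inter-cantilever axis. Extent is
  the outer envelope — an internal hole does not reduce width.

A gap is *closed* below 100 µm² (about the area of a single cell
cross-section; the assay itself never defines "closed" numerically, so the
threshold is exposed in `segmentation_params()`). After the first closed
frame, a later hole is accepted as a reopening only above twice that
threshold and is flagged; this guards against noise specks resurrecting a
closed wound.

## Closure kinetics

The closure model is piecewise linear: widening from the initial area to a
peak during the first ~1 h, then `A(t) = A_peak − r·(t − t_peak)` until the
closure threshold. `detect_widening()` takes the earliest maximum within the
first 25% of frames; `estimate_closure_rate()` fits ordinary least squares
from that peak to the last open frame and reports the negated slope with its
standard error and R². Fitting from the peak rather than from wounding
matters: the constant-rate description only holds after the widening phase.
The fit refuses windows shorter than 4 frames and all-closed series.

`relative_closure()` compares a treated tissue to vehicle controls as the
fraction of peak area closed by an evaluation time (default 10 h), divided
by the control mean of the same fraction — a series against itself is
exactly 1. Whether one should normalise fractions or fitted slopes is
genuinely open; we default to fractions (robust to late nonlinearity when a
drug halts closure entirely) and provide `method = "slope"`. Normalisation
is within-run: controls from the same experiment, not pooled.

## Nuclear tracking and directionality

Spots are detected per frame by scale-normalised Laplacian-of-Gaussian
filtering (σ matched to the nuclear radius, default 3 px), 8-neighbour local
maxima above a response threshold, sub-pixel refinement by response-weighted
centroid, and merging of detections within one σ. Linking is greedy
globally-shortest-first between consecutive frames with a 20 µm cap per
30-min step — at nuclear densities where the per-step displacement is below
half the inter-cell spacing this is equivalent to optimal assignment and far
easier to audit. There is no gap closing across missing frames; a vanished
spot ends its track.

Each track is annotated over an analysis interval with its net displacement,
the **radial migration angle** between that displacement and the unit vector
from the track start toward the gap centroid, folded to [0, 180]° (the
windrose axis labels only 0° and 90°, leaving the fold convention open; we
fold so 180° is motion directly away from the gap), the per-track maximum
frame-to-frame speed (the assay reports "maximum speed" without defining it;
this is our reading, stated here prominently), and a location class from the
track's mean distance to the gap boundary: ≤ 20 µm is *edge*, ≥ 100 µm is
*distal*. Windrose bins default to 20° anchored at 0°, which puts 90° at a
bin centre.

The analysis interval deserves a note: a cell circulating tangentially
subtends an arc, so its net-displacement chord tilts away from 90° by half
the subtended angle. Over a 24 h interval that tilt is tens of degrees; over
the default 0–2 h interval it is under 8° at the radii of these wounds.
Interval choice is therefore exposed everywhere and defaults short.

## Tension from cantilever beads

Beads are re-localised per frame by the background-subtracted
intensity-weighted centroid within a 6 µm search window around their
previous position; a window that loses signal flags the bead lost and drops
it from the tension computation. Deflection per bead is displacement from
the collagenase-baseline rest position projected on the inter-cantilever
axis and signed toward the tissue midline — off-axis jitter is noise, not
load; a `magnitude` mode reproduces the unprojected convention. Cantilever
deflection is the mean over its valid beads, and

> tension(t) = k · (δ₀(t) + δ₁(t)),  k = 2.67 µN µm⁻¹

with the baseline tension averaged over pre-wound frames and
`normalize_tension()` mapping it to 1.

## The synthetic scene generator

`render_scene()` draws three calibrated 16-bit channels emulating the assay:

* **tissue**: a bright band spanning the two cap positions minus an
  elliptical gap whose area follows the analytic trajectory exactly; the
  fresh wound boundary carries a random radial Fourier perturbation
  (modes 3–8, 6% amplitude) that decays to zero over the widening hour,
  emulating edge smoothing. The perturbation is re-normalised so the
  enclosed area is unchanged, and edges are anti-aliased over one pixel.
* **nuclei**: Gaussian spots (σ = 3 µm) at the ground-truth cell positions.
  Edge cells are seeded just outside the boundary and take exact tangential
  steps (fixed random orbit direction per cell); distal cells are seeded at
  least 100 µm from the boundary and step straight toward the centroid,
  halting at the current boundary. Isotropic Gaussian velocity noise
  (2 µm h⁻¹ s.d.) is added. Cells neither divide nor die — closure in this
  assay is proliferation-independent.
* **beads**: Gaussian spots displaced toward the midline by
  `tension/(2k)`, i.e. the tension is split equally across the two
  cantilevers, with rest positions defining the collagenase baseline. The
  tension profile is piecewise linear through baseline (6 µN) → post-wound
  minimum (3 µN at the first post-wound frame) → peak (8 µN at 10 h) →
  plateau (5.5 µN); the assay reports this shape only qualitatively, and
  these levels are our choice of a representative profile.

Additive Gaussian intensity noise (default s.d. 0.05, ~10% of the
tissue-background contrast) is applied to every channel and the result is
quantised to the 16-bit grid, so TIFF round trips are bit-exact. All
randomness flows from the single config seed; identical configs give
bit-identical stacks.

Defaults are the study conditions: 600×600 px at 1 µm/px, 30-min frames for
24 h (49 frames), a 30,000 µm² initial gap widening 10% over 1 h and closing
at 1,344 µm² h⁻¹ with aspect ratio 1.5, 200 cells, and 4 beads per
cantilever. Parameters the assay never quantifies — edge-band width (20 µm),
tangential and radial speeds (10 and 5 µm h⁻¹), the edge fraction of tracked
cells (0.15, consistent with a uniform nuclear density and the small area of
the edge band relative to the tissue), bead count and spot optics — are free
parameters documented in `scene_config()` and chosen once.

### What the generator does and does not emulate

It reproduces the geometry and dynamics the analysis assumes: an enclosed
elliptical gap with prescribed area kinetics and stationary centroid,
class-structured migration, and rigid bead displacement proportional to
tension. It does **not** simulate mechanics (no agent-based contraction, no
fibronectin deposition, no coupling between migration and closure), does not
deform the tissue texture (the band is homogeneous; real phase-contrast
tissue has fibrous texture that makes Otsu segmentation harder), and its
noise is white Gaussian rather than photon-limited. Passing recovery tests
therefore demonstrates correctness of the quantification machinery under the
assumed geometry, not robustness to every real-world imaging pathology.

One known generator artifact: distal cells that reach the shrinking boundary
halt there, and late in a recording several may crowd within a couple of
micrometres. Under velocity noise this crowding can swap greedy links
(identity accuracy drops from ~98% noiseless to ~94% at the default noise on
a full 24 h scene) — a statement about the generator's pile-up, not about
tracking at realistic spacings, which is why the linking validation uses the
noiseless construction.

## Numerical choices and degenerate inputs

* Log transform in confocal preprocessing is `log(1 + x)` so zero
  intensities stay defined; a constant projection rescales to 1 (or 0 when
  identically zero).
* Calibration (µm/px, h/frame) is always supplied by the caller, never read
  from TIFF tags, for determinism across acquisition dialects. Pixel
  coordinates are 0-based (row, col) at pixel centres; all public tables are
  in µm and hours.
* Otsu thresholding uses each frame's own intensity range, making measured
  areas invariant to positive rescaling of intensities.
* An empty gap yields area 0, `closed = TRUE` and `NA` ellipse fields; a
  sub-3-pixel gap fits no ellipse; a flat frame segments to an empty mask.
* Widening-peak ties take the earliest frame. Equal-area hole ties take the
  hole nearest the previous centroid.
* R² of an exactly constant fitted series is reported as 1 (zero residual
  against zero variance).

## Problem sizes used in validation

The test suite renders 300×300 px, 12 h scenes (7,000 µm² gaps) for unit
checks and full 600×600 px, 49-frame scenes for the end-to-end
parameter-recovery checks: closure-rate recovery within the ±150 µm² h⁻¹
reporting band at 10% noise, rate invariance across 15k/25k/35k µm² initial
gaps, ellipse and area agreement with an exhaustive-summation oracle within
2%, tension recovery within 5% relative RMS with the min < plateau <
baseline < peak ordering, windrose modes at the bins containing 90° (edge)
and 0° (distal), ≥ 95% link-identity accuracy on 200-cell noiseless scenes,
and bit-identical reproduction from identical seeds. `scripts/acceptance.R`
recomputes all of these from scratch.

## Limitations

Beyond the generator's scope above: the pipeline quantifies projected 2D
masks (no z-resolved morphometrics); the greedy linker has no gap closing or
merge/split handling, so a missed detection splits a track; spring-constant
calibration is out of scope (k is an input); and multi-condition statistics
are deliberately left to external tools — the package exports per-track and
per-tissue tables instead.
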