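# microwound

Quantification pipeline for wound repair in engineered 3D microtissues —
sub-millimetre fibroblast–collagen constructs suspended between flexible
cantilevers, wounded microsurgically and imaged by time-lapse microscopy.
It is written for experimenters running (or simulating) this assay who need
per-tissue and per-track numbers they can feed into downstream statistics.

The package covers the assay's three readouts end to end:

* **Gap morphometrics** — per-frame segmentation of the tissue by a
  brightness threshold, extraction of the tissue-enclosed gap, and
  measurement of area *A*, centroid, moment-fitted ellipse (semi-axes
  *a*, *b* from `2·sqrt` of the covariance eigenvalues), circularity
  `4πA/P²`, and tissue width.
* **Closure kinetics** — the gap widens briefly, then closes linearly:
  `A(t) = A_peak − r·(t − t_peak)`. OLS from the detected widening peak
  gives the closure rate *r* (µm² h⁻¹) with standard error and R², plus
  closure time and relative closure versus vehicle controls.
* **Migration directionality** — LoG nuclear spot detection, greedy
  nearest-first track linking, per-track radial migration angles
  (0° = toward the gap, 90° = tangential), edge/distal classification by
  distance to the wound boundary, windrose histograms, and per-track
  maximum speeds.
* **Tissue tension** — bead tracking on the cantilever caps and
  `T(t) = k·(δ₀ + δ₁)` with spring constant *k* (µN µm⁻¹), deflections
  measured from collagenase-baseline rest positions.
* **Synthetic scenes** — a seeded generator renders tissue/nuclei/bead
  channels with exact ground truth (analytic gap trajectory, constructed
  tracks, tension-driven bead displacement), so every stage above is
  validated by parameter recovery.

## Worked example

Simulate a default scene (30,000 µm² gap, 30-min frames for 24 h, 10%
intensity noise, closure at 1,344 µm² h⁻¹) and recover the closure rate:

```r
library(microwound)

cfg    <- scene_config(seed = 42)
scene  <- render_scene(cfg)
morpho <- morphometrics_series(scene$tissue)
morpho[1:4, c("frame", "t_h", "area_um2", "a_um", "b_um",
              "circularity", "closed")]
#> # A tibble: 4 × 7
#>   frame   t_h area_um2  a_um  b_um circularity closed
#>   <int> <dbl>    <dbl> <dbl> <dbl>       <dbl> <lgl>
#> 1     1   0      29986  121.  80.7       0.828 FALSE
#> 2     2   0.5    31476  123.  82.0       0.909 FALSE
#> 3     3   1      32987  125.  83.7       0.938 FALSE
#> 4     4   1.5    32332  124.  82.8       0.938 FALSE

fit <- estimate_closure_rate(morpho)
fit
#> <closure_kinetics> rate 1343.7 +/- 0.2 um^2/h (R^2 = 1.0000)
#>   fit window 1-24 h (47 frames), peak 32987 um^2 at 1 h
#>   closure time NA h, centroid drift 0.51 um
```

The measured initial area (29,986 µm²) matches the configured gap, the
widening peak is found at 1 h, and the fitted rate (1,343.7 µm² h⁻¹)
recovers the generative 1,344 µm² h⁻¹ — note the low circularity of the
first frame (rough fresh cut) rising as the edge smoothens. `glance(fit)`
returns the same fields as a one-row tibble; `autoplot(morpho, fit)` plots
the area series with the fitted line, and `tidy(fit)` gives the
broom-style coefficient table.

Downstream stages follow the same pattern: `detect_nuclei_series()` |>
`link_tracks()` |> `migration_stats()` |> `windrose()` for directionality
(plot with `plot_windrose()`), and `track_beads()` |> `deflections()` |>
`total_tension()` |> `normalize_tension()` for tension
(`autoplot()` shows the time course against the pre-wound baseline).

A command-line wrapper with `simulate`, `measure`, `kinetics`, `track` and
`tension` subcommands is installed at `inst/cli/microwound.R`
(`system.file("cli", "microwound.R", package = "microwound")`); it reads
TIFF stacks plus a YAML config and writes CSV/JSON.

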