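---
title: "Correcting polygon contour annotations with llpc: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting polygon contour annotations with llpc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(llpc)
```

## The problem

A polygon annotation of a cell contour encodes two different kinds of
information. The *semantics* — which object is outlined, and on which side
of an overlap the boundary runs — come from the human and are expensive
and reliable. The *geometry* — where exactly each vertex sits — is cheap
and noisy: clicked points drift off the intensity boundary, vertices are
sparse along straight runs, and the polygon is not smooth. `llpc` corrects
the geometry while deliberately never touching the semantics: each contour
is processed in isolation, points move only along the local normal, never
farther than a radius `r`, and only where the image actually shows a
boundary.

## The model, stage by stage

### Guidance field

The guidance signal is the gradient magnitude of the Gaussian-smoothed
image, min–max normalized to `[0, 255]`. Two choices here are ours, since
the method itself only presumes "a gradient image after Gaussian
smoothing":

* **Smoothing scale** `gradientSigma = 2` px, kernel truncated at 3σ.
  Small enough that the gradient ridge stays within a pixel of the true
  boundary at the search radii in play; large enough to suppress
  pixel-level noise from creating spurious candidate peaks.
* **Normalization to `[0, 255]`.** The gating threshold `lambdaT = 4` is
  expressed in gradient units; pinning the field to an 8-bit-like range
  keeps that threshold meaningful for any input bit depth, and makes a
  scaled copy of an image produce the identical field.

Smoothing uses a direct separable convolution with replicate borders
rather than an FFT: direct summation makes the field bit-identical under
integer translation of the content, which we assert in the tests.
Gradients are central differences; sampling at non-integer candidate
positions is bilinear, with out-of-domain points clamped to the border so
edge-touching annotations remain valid inputs.

### Gradient-guided point correction

For each vertex, `2r + 1` candidates sit at unit offsets `t ∈ {−r, …, r}`
along the contour normal (the perpendicular of the central chord
`x_{i+1} − x_{i−1}`; its sign is irrelevant because candidates span both
sides). Candidates are scored by `ω_t · g`, with `ω_t = K(|t|, h1)` a
Gaussian kernel of bandwidth `h1 = r/2`. The vertex moves to the top
candidate only when the weighted gradient variation
`Δ = |max(ω·g) − min(ω·g)| − λ_t·max(ω)` is positive. Because offset 0 is
itself a candidate, `max(ω) = K(0, h1)` exactly, which makes `λ_t` a clean
per-point threshold: an all-flat neighborhood gives
`Δ = −λ_t·K(0, h1) < 0` and the point stays put. That is what preserves
annotations inside overlaps, where translucent stacking leaves only weak
gradients.

Remaining free choices, fixed once and tested: candidates are spaced at
1 px (the pixel resolution; finer spacing cannot add information to a
bilinearly sampled field); exact score ties resolve to the smallest
absolute offset and then to the negative side, so the correction is
deterministic and displacement-minimal; and all vertices are corrected
from the *input* contour's geometry rather than sequentially, so the
result does not depend on traversal order.

### Point interpolation

Pairs farther apart than `2·gap` (strictly) receive the minimal number of
evenly spaced collinear points such that the new spacings fall below
`gap`; `k = ⌊d/gap⌋` points suffice. Pairs at or below `2·gap` are left
alone — a consequence of the selection rule — so the contour-wide
guarantee after this stage is spacing `≤ 2·gap`, with `< gap` on every
pair that was actually densified. In the regime the stage exists for
(hand-clicked vertices several pixels apart with `gap = 1`) every pair is
densified and the strict `< gap` bound holds throughout. Original
vertices always survive as a subsequence, so interpolation never discards
information.

### Local point smoothing

Every point `i` is re-estimated from the window of `ng` consecutive
points holding `i` at its center position. `ng = 14` is even, so a
centered window is ambiguous; we place `rf = ⌊(ng−1)/2⌋ = 6` points
before `i` and 7 after, consistent with the group-radius definition, and
test that wrapped windows behave identically to unwrapped ones. The
window is rotated into a frame whose x-axis passes through its endpoints
(a window whose endpoints coincide falls back to the principal axis of
the window's spread), a kernel-weighted linear regression with normalized
weights and bandwidth `h2 = rf/2` is solved in closed form, and only the
center point's frame ordinate is replaced. A singular weighted design
(all abscissas equal) leaves the point unchanged rather than failing.
Updates are parallel: all windows come from the input contour.

The smoother is exact on collinear windows, equivariant under rigid
motions (the frame is intrinsic), and contractive on noise — properties
the test suite checks directly.

### Orchestration

The stages run in the fixed order GPC → PI → LPS; point correction acts
on the original sparse vertices only (interpolated points are smoothed
but never gradient-corrected). The gradient field is computed once per
image and shared by all shapes. Each stage can be disabled via
`llpcConfig()` for ablation studies; with all three disabled the pipeline
is the identity. Everything is deterministic: the same inputs and
configuration produce bit-identical outputs.

## Parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `r` | 15 | px | maximum correction range along the normal |
| `lambdaT` | 4 | gradient units | gating threshold on weighted gradient variation |
| `h1` | `r/2` | px | candidate-weight bandwidth; penalizes far candidates |
| `gap` | 1 | px | target spacing after interpolation |
| `ng` | 14 | points | smoothing window size |
| `h2` | `rf/2` | px | regression bandwidth inside the window |
| `gradientSigma` | 2 | px | smoothing scale of the guidance field |

`r` trades correction range against susceptibility to adjacent edges; the
kernel weighting is what allows a generous `r` without being captured by
a neighboring cell's stronger gradient. `lambdaT` controls how much
gradient evidence is needed before a human point is overridden. `ng`
sets the smoothing scale in points, which at `gap = 1` is also a scale in
pixels. `h1` and `h2` are recomputed when `r` or `ng` is overridden,
unless pinned explicitly.

## The synthetic test bed

Real reference datasets for this task have no exact ground truth — that
is the problem being solved — so the package ships a generator whose
truth is analytic. Scenes are translucent elliptical cytoplasms with a
darker nucleus strictly inside, Gaussian-blurred boundaries (default
σ = 2 px), and seeded Gaussian pixel noise (default σ = 5). Translucent
stacking makes overlap regions visible but weak in gradient, exercising
the gating branch. Cell sizes default to semi-axes of 105–165 px —
consistent with high-magnification cytology images of a few megapixels,
the scale at which a 14-point smoothing window spans a small fraction of
a nucleus contour.

The annotation-error model mimics a tracing hand: vertices sampled at a
mean arc spacing of 8 px, densified where curvature is high, displaced
along the true normal by a *smooth* zero-mean random field (a 5-harmonic
Fourier series in the contour parameter, marginal sd `jitterSigma = 3`,
clamped at `jitterCap = 10`). The field is smooth because human drift is
slowly varying along a stroke; it is capped below `r` so errors remain
recoverable in principle. With cap/σ ≈ 3.3 the clamped marginal is
indistinguishable from a truncated normal (< 0.1 % in RMS), which gives
the analytic moment the tests compare against. Seeds are split per cell
and per contour through a counter scheme, so adding a cell to a scene
does not reshuffle the noise of existing cells.

What the generator does *not* emulate: staining texture, debris and
mucus artifacts, non-elliptical cell shapes, and spatially correlated
sensor noise. Passing the synthetic suite therefore demonstrates the
geometric behavior of the pipeline — recovery of normal displacement
within `r`, preservation of weak-gradient positions, smoothing — not
robustness to every real-world artifact.

## Measuring correction quality

`contourDistance()` measures point-to-polyline distance against the dense
truth; `smoothnessEnergy()` is the mean squared discrete curvature after
uniform arc-length resampling, making it invariant to point density and
rigid motion. For pipeline comparisons, `evaluateAgainstTruth()` also
resamples every contour uniformly in arc length before measuring
distance. This choice matters: the pipeline's output has roughly eight
times as many points as its input, and a per-point comparison would score
a sparse polygon only at its (accurately snapped) vertices while scoring
a densified polygon along every chord. Resampling compares the contours
as curves, which is the quantity an edge label actually represents.

On the canonical five-scene suite at the default conditions the full
pipeline removes 70–80 % of the RMS annotation error (the acceptance
script recomputes this for any seed), and smoothing reduces the curvature
energy of the point-corrected contour by roughly a factor of five. Two
finer directional comparisons deserve honesty: point correction alone
already achieves essentially all of the *distance* recovery, with
smoothing contributing smoothness rather than additional proximity — the
correction residual left by the discrete, kernel-weighted argmax is
largely smooth along the contour, so a local linear fit cannot reduce it
further. And mild smoothing *without* point correction shaves a percent
or two off the RMS of our smooth-drift error model rather than leaving
it untouched: a local linear fit slightly trims the drift field at its
extrema. Both margins are small compared to the 70–80 % effect of the
full pipeline, but they are real properties of the geometry, and the
test suite states them at their measured values rather than idealized
ones.

## Numerical choices and degenerate inputs

* Coordinates are 0-based, x = column, y = row, pixel centers at
  integers; all I/O and rasterization share this convention.
* Normal estimation falls back from the central chord to the forward
  chord when the neighbors coincide; a fully degenerate vertex is a
  validation error.
* Contours shorter than `ng` smooth with the largest odd window that
  fits, with a warning recorded in the correction report.
* Non-polygon shapes and polygons with fewer than 3 points pass through
  the pipeline untouched, flagged in the report.
* Mask rasterization uses even-odd filling at integer pixel centers with
  a half-open tie rule; edge rasterization uses integer line drawing
  after rounding, with no anti-aliasing, because binary ground truth
  must stay binary.
* Patch windows are half-open `[x0, x1) × [y0, y1)`; patch sizes must
  divide the image exactly (no partial patches), and the shifted grids
  use half-patch offsets.
* Polygon clipping at patch borders is Sutherland–Hodgman against the
  window rectangle, keeping closed pieces in window-local coordinates.

## Problem sizes

The test suite and the acceptance script run entirely on generated data:
scenes between 320² and 1152² pixels with up to five cells, contours of
a few hundred to a few thousand points after densification, a thousand
randomized argmax-oracle cases and a hundred-plus regression-oracle
cases. A full acceptance run takes well under a minute on one CPU core.

## Known limitations

* Parameters are global; cytoplasm and nucleus contours use the same
  `r`, `λ_t` and `ng`, and nothing adapts per point.
* The search is strictly 1-D along the normal; a vertex whose true
  boundary lies outside the normal line (e.g. after a gross topology
  error) cannot be recovered.
* Correction quality degrades where two true edges run within `r` of
  each other with comparable strength; the kernel weighting mitigates
  but does not eliminate capture by the wrong edge.
* The curve-stitching formulation of piecewise fitting (overlapping
  groups with stride > 1 and curve resampling) is intentionally not
  implemented; the per-point stride-1 smoother supersedes it and avoids
  splice artifacts by construction.
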