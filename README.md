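# llpc — local label point correction for cell contour annotations

Hand-drawn polygon annotations of cell contours in microscopy images are
systematically imperfect: the clicked vertices drift off the true boundary,
sparse clicks leave long straight runs, and the resulting polygons are not
smooth. For edge-detection and segmentation ground truth this matters — a
label a few pixels off the gradient ridge teaches a detector the wrong
boundary. `llpc` refines such annotations automatically while preserving
the human's semantic decisions (which cell, which side of an overlap), a
property that global refiners such as active contours or dense CRFs do not
offer for overlapping objects.

The package is aimed at people building labeled microscopy datasets —
overlapping cervical cells being the motivating case — and at anyone who
wants a reproducible, seeded test bed for annotation-refinement methods.

## Method

Each closed contour `{x_i}` is processed in three deterministic stages:

1. **Gradient-guided point correction (GPC).** Let `g(x, y)` be the
   gradient magnitude of the Gaussian-smoothed image, normalized to
   `[0, 255]`. For every label point, `2r + 1` candidates are placed at
   unit offsets `t ∈ {−r, …, r}` along the contour normal and scored by
   `ω_t · g`, with Gaussian kernel weights `ω_t = K(|t|, h1)`,
   `K(x, h) = κ(x/h)/h`. The point moves to the best candidate only when
   the weighted gradient variation exceeds a threshold:

   `Δ = |max_t(ω_t g_t) − min_t(ω_t g_t)| − λ_t · max_t(ω_t) > 0`,

   so points in weak-gradient regions (e.g. inside overlaps) keep their
   human-assigned position.
2. **Point interpolation (PI).** Every circularly adjacent pair farther
   apart than `2·gap` receives the minimal number of evenly spaced
   collinear points so the new spacings fall below `gap`.
3. **Local point smoothing (LPS).** Every point is re-estimated from its
   window of `ng` consecutive points: the window is rotated into a local
   frame whose x-axis joins its endpoints, a kernel-weighted linear
   regression `β = (XᵀωX)⁻¹XᵀωY` is solved with normalized weights
   `ω_j(x) = K(|x − x_j|, h2) / Σ_m K(|x − x_m|, h2)`, and only the center
   point's ordinate is replaced by the fitted value. All windows are drawn
   from the input contour, so the update is parallel and order-independent.

Defaults: `r = 15`, `λ_t = 4`, `h1 = r/2`, `gap = 1`, `ng = 14`,
`h2 = rf/2` with group radius `rf = ⌊(ng − 1)/2⌋`, gradient scale
`σ = 2` px. Each stage can be disabled independently for ablations.

The package also provides labelme-dialect annotation I/O, binary edge and
per-instance mask rasterization, the overlapping-grid dataset cutter
(`(2a−1)(2b−1)` half-open windows per image, so every base-grid seam is
interior to some shifted window), a CLI, and a seeded synthetic
overlapping-cell generator with analytic ground truth and quality metrics.

## Worked example

```r
library(llpc)

spec  <- sceneSpec(width = 320, height = 320, nCells = 1,
                   cytoAxes = c(70, 100), overlap = FALSE, seed = 42)
scene <- renderScene(spec)                       # image + analytic truth
annot <- perturbAnnotation(scene$truth,          # "human" annotation
                           perturbationSpec(seed = 42))
annot
#> AnnotationDocument: 320 x 320 px, 2 shape(s)
#>   cytoplasm: 1, nucleus: 1

cfg <- llpcConfig()
cfg
#> LLPCConfig: r = 15, lambdaT = 4, h1 = 7.5 | gap = 1 | ng = 14, h2 = 3 | sigma = 2
#>   stages: GPC on, PI on, LPS on

res <- correctAnnotation(annot, scene$image, cfg)
str(res$report$totals)
#> List of 6
#>  $ nShapes           : int 2
#>  $ nPointsIn         : int 81
#>  $ nMovedByGPC       : int 69
#>  $ nPointsInserted   : int 615
#>  $ nPointsOut        : int 696
#>  $ maxGPCDisplacement: num 6
```

69 of the 81 annotated points sat in strong-gradient regions and were
snapped to the weighted gradient peak (never farther than `r`; here at most
6 px); interpolation then densified the polygons to 696 points before
smoothing. Measuring against the analytic truth:

```r
before <- evaluateAgainstTruth(annot, scene$truth)
after  <- evaluateAgainstTruth(res$document, scene$truth)
sprintf("RMS distance to truth: %.3f px -> %.3f px", before$rms, after$rms)
#> [1] "RMS distance to truth: 3.009 px -> 0.579 px"   # 81% lower
sprintf("smoothness energy:     %.2e -> %.2e", before$energy, after$energy)
#> [1] "smoothness energy:     1.76e-02 -> 9.65e-04"
```

The corrected document can be written back (`writeAnnotation()`),
rasterized to edge maps (`rasterizeEdges()`) or per-instance masks
(`rasterizeMasks()`), or cut into training patches
(`buildPatchGrid()` + `cutImageAndLabels()`). The same operations are
available from the shell via `inst/scripts/llpc`
(`correct`, `cut`, `synth`, `eval` subcommands).

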