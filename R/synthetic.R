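# Synthetic overlapping-cell scenes with analytic ground truth, a
# human-like annotation perturbation model, and correction-quality metrics.

#' Specification of a synthetic overlapping-cell scene
#'
#' Cells are rendered as translucent elliptical cytoplasms with a darker
#' elliptical nucleus strictly inside, on a flat background; boundaries are
#' Gaussian-blurred and seeded Gaussian noise is added. Translucent
#' stacking keeps overlapping regions visible while weakening the gradient
#' where contours cross other cells, which exercises the weak-gradient
#' preservation branch of point correction. Ellipses keep the ground truth
#' analytic.
#'
#' @param width,height canvas size, px.
#' @param nCells number of cells.
#' @param cytoAxes range (min, max) of cytoplasm semi-axes, px.
#' @param nucleusFrac range of nucleus semi-axes as a fraction of the
#'   cytoplasm's.
#' @param overlap allow cytoplasms to overlap.
#' @param background background intensity level.
#' @param cellContrast range of per-cell cytoplasm intensity increments.
#' @param nucleusContrast additional nucleus intensity increment.
#' @param blurSigma boundary blur scale, px (0 = hard edges).
#' @param noiseSigma additive Gaussian noise sd, intensity units.
#' @param seed integer; fully determines the scene.
#' @return list of class `SceneSpec`.
#' @export
sceneSpec <- function(width = 864, height = 864, nCells = 2,
                      cytoAxes = c(105, 165), nucleusFrac = c(0.30, 0.45),
                      overlap = TRUE, background = 40,
                      cellContrast = c(50, 80), nucleusContrast = 60,
                      blurSigma = 2, noiseSigma = 5, seed = 1) {
  stopifnot(width >= 32, height >= 32, nCells >= 0,
            all(cytoAxes > 0), diff(cytoAxes) >= 0,
            all(nucleusFrac > 0), all(nucleusFrac < 1),
            blurSigma >= 0, noiseSigma >= 0)
  structure(list(width = width, height = height, nCells = nCells,
                 cytoAxes = cytoAxes, nucleusFrac = nucleusFrac,
                 overlap = isTRUE(overlap), background = background,
                 cellContrast = cellContrast,
                 nucleusContrast = nucleusContrast, blurSigma = blurSigma,
                 noiseSigma = noiseSigma, seed = as.integer(seed)),
            class = "SceneSpec")
}

#' Human-like annotation perturbation model
#'
#' Vertices are sampled along each true contour at a mean arc spacing, with
#' curvature-weighted densification (denser where the contour bends, as
#' human annotators do). Each vertex is displaced along the true outward
#' normal by a smooth, zero-mean random field: a low-order Fourier series
#' in the contour parameter with marginal standard deviation
#' `jitterSigma`, clamped at `jitterCap`. The smooth field models the
#' slowly varying error of a tracing hand rather than independent per-point
#' noise.
#'
#' @param spacing mean arc length between annotated points, px.
#' @param jitterSigma marginal sd of the normal displacement, px.
#' @param jitterCap hard cap on the displacement magnitude, px (keep below
#'   the search radius `r` of the correction under test so errors remain
#'   recoverable).
#' @param curvatureBoost strength of curvature-dependent densification
#'   (0 = uniform spacing).
#' @param harmonics number of Fourier harmonics in the error field.
#' @param seed integer seed.
#' @return list of class `PerturbationSpec`.
#' @export
perturbationSpec <- function(spacing = 8, jitterSigma = 3, jitterCap = 10,
                             curvatureBoost = 1, harmonics = 5, seed = 1) {
  stopifnot(spacing > 0, jitterSigma >= 0, jitterCap >= 0, harmonics >= 1)
  structure(list(spacing = spacing, jitterSigma = jitterSigma,
                 jitterCap = jitterCap, curvatureBoost = curvatureBoost,
                 harmonics = as.integer(harmonics), seed = as.integer(seed)),
            class = "PerturbationSpec")
}

.ellipsePoint <- function(t, ell) {
  ca <- cos(ell$angle); sa <- sin(ell$angle)
  ex <- ell$axes[1] * cos(t); ey <- ell$axes[2] * sin(t)
  cbind(ell$center[1] + ca * ex - sa * ey,
        ell$center[2] + sa * ex + ca * ey)
}

.ellipseNormal <- function(t, ell) {
  # outward normal of (a cos t, b sin t) is prop. to (b cos t, a sin t)
  ca <- cos(ell$angle); sa <- sin(ell$angle)
  nx <- ell$axes[2] * cos(t); ny <- ell$axes[1] * sin(t)
  n <- cbind(ca * nx - sa * ny, sa * nx + ca * ny)
  n / .rowNorms(n)
}

.ellipseContour <- function(ell, n = 720) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  .ellipsePoint(t, ell)
}

.insideEllipse <- function(X, Y, ell) {
  ca <- cos(ell$angle); sa <- sin(ell$angle)
  dx <- X - ell$center[1]; dy <- Y - ell$center[2]
  u <- (ca * dx + sa * dy) / ell$axes[1]
  v <- (-sa * dx + ca * dy) / ell$axes[2]
  u * u + v * v <= 1
}

#' Render a synthetic scene with exact ground truth
#'
#' Deterministic given the spec's seed; per-cell parameters are drawn from
#' counter-derived sub-seeds so adding a cell does not reshuffle earlier
#' cells.
#'
#' @param spec a [sceneSpec()].
#' @return list with `image` (H x W matrix, `[0, 255]`) and `truth`
#'   (`width`, `height`, and per-cell analytic ellipse parameters plus
#'   densely sampled true contours, 720 points each).
#' @export
renderScene <- function(spec) {
  W <- spec$width; H <- spec$height
  cells <- list()
  for (k in seq_len(spec$nCells)) {
    placed <- NULL
    for (attempt in 1:300) {
      cand <- withr::with_seed(.subSeed(spec$seed, k, attempt), {
        ax <- sort(stats::runif(2, spec$cytoAxes[1], spec$cytoAxes[2]),
                   decreasing = TRUE)
        margin <- ax[1] + 4
        if (2 * margin >= min(W, H)) stop("cells too large for the canvas")
        list(center = c(stats::runif(1, margin, W - margin),
                        stats::runif(1, margin, H - margin)),
             axes = ax,
             angle = stats::runif(1, 0, pi),
             contrast = stats::runif(1, spec$cellContrast[1],
                                     spec$cellContrast[2]),
             frac = stats::runif(1, spec$nucleusFrac[1],
                                 spec$nucleusFrac[2]),
             nucOff = stats::runif(2, -1, 1))
      })
      ok <- TRUE
      for (prev in cells) {
        cd <- sqrt(sum((cand$center - prev$cyto$center)^2))
        lim <- if (spec$overlap) 0.45 * (cand$axes[1] + prev$cyto$axes[1])
               else cand$axes[1] + prev$cyto$axes[1]
        if (cd <= lim) { ok <- FALSE; break }
      }
      if (ok) { placed <- cand; break }
    }
    if (is.null(placed))
      stop(sprintf("could not place cell %d after 300 attempts", k))
    cyto <- list(center = placed$center, axes = placed$axes,
                 angle = placed$angle)
    nucAxes <- placed$axes * placed$frac
    maxOff <- 0.4 * (placed$axes[2] - nucAxes[1])
    nucleus <- list(center = placed$center +
                      pmax(-maxOff, pmin(maxOff, placed$nucOff * maxOff)),
                    axes = nucAxes, angle = placed$angle)
    cells[[k]] <- list(cyto = cyto, nucleus = nucleus,
                       contrast = placed$contrast,
                       cytoContour = .ellipseContour(cyto),
                       nucleusContour = .ellipseContour(nucleus))
  }
  X <- matrix(rep(0:(W - 1), each = H), H, W)
  Y <- matrix(rep(0:(H - 1), times = W), H, W)
  img <- matrix(spec$background, H, W)
  for (cell in cells) {
    img <- img + cell$contrast * .insideEllipse(X, Y, cell$cyto)
    img <- img + spec$nucleusContrast * .insideEllipse(X, Y, cell$nucleus)
  }
  if (spec$blurSigma > 0) img <- .gaussSmooth(img, spec$blurSigma)
  if (spec$noiseSigma > 0) {
    noise <- withr::with_seed(.subSeed(spec$seed, 0, 999),
                              stats::rnorm(H * W, 0, spec$noiseSigma))
    img <- img + matrix(noise, H, W)
  }
  img <- pmin(pmax(img, 0), 255)
  list(image = img,
       truth = list(width = W, height = H, cells = cells))
}

# Curvature of the ellipse parameterization at parameter t.
.ellipseCurvature <- function(t, ell) {
  a <- ell$axes[1]; b <- ell$axes[2]
  a * b / (a^2 * sin(t)^2 + b^2 * cos(t)^2)^1.5
}

.perturbOneContour <- function(ell, pspec, seed) {
  withr::with_seed(seed, {
    nDense <- 2000L
    t <- seq(0, 2 * pi, length.out = nDense + 1L)[-(nDense + 1L)]
    p <- .ellipsePoint(t, ell)
    ds <- .rowNorms(p[c(2:nDense, 1), , drop = FALSE] - p)
    L <- sum(ds)
    kap <- .ellipseCurvature(t, ell)
    w <- 1 + pspec$curvatureBoost * (kap / mean(kap) - 1)
    w <- pmax(w, 0.2)
    cw <- cumsum(w * ds)
    M <- max(8L, round(L / pspec$spacing))
    phase <- stats::runif(1)
    targets <- ((phase + (0:(M - 1L)) / M) %% 1) * cw[nDense]
    ti <- t[pmin(pmax(1L, findInterval(targets, cw) + 1L), nDense)]
    ti <- sort(ti)
    K <- pspec$harmonics
    ab <- stats::rnorm(2 * K, 0, pspec$jitterSigma / sqrt(K))
    e <- rep(0, length(ti))
    for (j in seq_len(K))
      e <- e + ab[2 * j - 1] * cos(j * ti) + ab[2 * j] * sin(j * ti)
    e <- pmax(-pspec$jitterCap, pmin(pspec$jitterCap, e))
    .ellipsePoint(ti, ell) + e * .ellipseNormal(ti, ell)
  })
}

#' Perturb ground-truth contours into a human-like annotation
#'
#' Applies the [perturbationSpec()] model to every cytoplasm and nucleus of
#' a rendered scene's ground truth, producing a labelme-style annotation
#' document. Shape order is cell 1 cytoplasm, cell 1 nucleus, cell 2
#' cytoplasm, ... matching the truth's cell order. Seeded per contour so
#' scenes are reproducible and extensible.
#'
#' @param truth the `truth` component of [renderScene()] output.
#' @param pspec a [perturbationSpec()].
#' @return An [AnnotationDocument-class].
#' @export
perturbAnnotation <- function(truth, pspec) {
  shapes <- list()
  for (k in seq_along(truth$cells)) {
    cell <- truth$cells[[k]]
    for (part in c("cyto", "nucleus")) {
      pts <- .perturbOneContour(cell[[part]], pspec,
                                .subSeed(pspec$seed, 1000L + k,
                                         if (part == "cyto") 0L else 500L))
      shapes[[length(shapes) + 1L]] <-
        Contour(pts, label = if (part == "cyto") "cytoplasm" else "nucleus",
                meta = list(cell = k))
    }
  }
  annotationDocument(shapes, imageHeight = truth$height,
                     imageWidth = truth$width, imagePath = "synthetic")
}

#' Distance of contour points to a reference polyline
#'
#' For each contour point, the Euclidean distance to the nearest segment of
#' the (closed) reference polyline; aggregated as mean, RMS and max. The
#' symmetric variant averages the statistics of both directions.
#'
#' @param contour a [Contour-class] or n x 2 matrix.
#' @param truth m x 2 matrix of densely sampled reference points.
#' @param symmetric also measure truth-to-contour and average.
#' @return named numeric `c(mean=, rms=, max=)` in px.
#' @export
contourDistance <- function(contour, truth, symmetric = FALSE) {
  p <- if (is(contour, "Contour")) contourPoints(contour) else as.matrix(contour)
  q <- as.matrix(truth)
  stopifnot(nrow(p) > 0, nrow(q) > 1)
  d <- .pointsToPolyline(p, q)
  res <- c(mean = mean(d), rms = sqrt(mean(d^2)), max = max(d))
  if (symmetric) {
    d2 <- .pointsToPolyline(q, p)
    res2 <- c(mean = mean(d2), rms = sqrt(mean(d2^2)), max = max(d2))
    res <- (res + res2) / 2
  }
  res
}

#' Mean squared discrete curvature of a contour
#'
#' The contour is resampled uniformly in arc length (making the measure
#' invariant to point density), then the squared norm of the second
#' difference divided by the squared spacing — a discrete curvature — is
#' averaged. Lower is smoother; invariant to rigid motion.
#'
#' @param contour a [Contour-class] or n x 2 matrix.
#' @param nResample number of resampling points.
#' @param closed treat the point sequence as a closed polygon.
#' @return scalar energy (px^-2).
#' @export
smoothnessEnergy <- function(contour, nResample = 256, closed = TRUE) {
  p <- if (is(contour, "Contour")) contourPoints(contour) else as.matrix(contour)
  stopifnot(nrow(p) >= 3)
  q <- .resamplePolyline(p, nResample, closed = closed)
  L <- sum(.rowNorms((if (closed) q[c(2:nrow(q), 1), ] else q[-1, , drop = FALSE]) -
                       (if (closed) q else q[-nrow(q), , drop = FALSE])))
  ds <- L / (if (closed) nResample else nResample - 1)
  if (ds <= 0) return(0)
  n <- nrow(q)
  if (closed) {
    d2 <- q[c(2:n, 1), ] - 2 * q + q[c(n, 1:(n - 1)), ]
  } else {
    d2 <- q[3:n, , drop = FALSE] - 2 * q[2:(n - 1), , drop = FALSE] +
      q[1:(n - 2), , drop = FALSE]
  }
  mean((rowSums(d2^2)) / ds^4)
}

#' Evaluate an annotation document against scene ground truth
#'
#' Pairs each shape with its cell's true cytoplasm or nucleus contour (via
#' the shape's `cell` meta field and label) and measures distance to truth
#' and smoothness. By default every contour is first resampled uniformly in
#' arc length, making the distance density-invariant so that sparse and
#' densified outputs are compared fairly as curves; set
#' `nResample = NULL` to measure the raw point sets instead. The pooled
#' RMS aggregates per-shape RMS values quadratically.
#'
#' @param doc an [AnnotationDocument-class] (e.g. from
#'   [perturbAnnotation()] or [correctAnnotation()]).
#' @param truth the `truth` component of [renderScene()] output.
#' @param nResample resampling density per contour, or `NULL`.
#' @return list with `perShape` (matrix of mean/rms/max/energy rows) and
#'   pooled `rms`, `mean`, `max`, `energy`.
#' @export
evaluateAgainstTruth <- function(doc, truth, nResample = 1440) {
  sh <- shapes(doc)
  st <- lapply(seq_along(sh), function(i) {
    s <- sh[[i]]
    cellIdx <- s@meta$cell %||% ((i + 1) %/% 2)
    cell <- truth$cells[[cellIdx]]
    ref <- if (identical(s@label, "nucleus")) cell$nucleusContour
           else cell$cytoContour
    p <- if (is.null(nResample)) contourPoints(s)
         else .resamplePolyline(contourPoints(s), nResample, closed = TRUE)
    c(contourDistance(p, ref), energy = smoothnessEnergy(s))
  })
  m <- do.call(rbind, st)
  list(perShape = m,
       rms = sqrt(mean(m[, "rms"]^2)),
       mean = mean(m[, "mean"]),
       max = max(m[, "max"]),
       energy = mean(m[, "energy"]))
}

#' Canonical synthetic scene pack
#'
#' Five seeded scene specifications spanning the regimes the corrector is
#' meant to handle: a single cell, a slightly overlapping pair, a heavily
#' overlapping pair, a five-cell mass, and a strongly blurred pair.
#'
#' @param seed base seed; each scene derives its own sub-seed.
#' @return named list of [sceneSpec()] objects.
#' @export
canonicalScenes <- function(seed = 1) {
  list(
    single = sceneSpec(nCells = 1, width = 768, height = 768,
                       overlap = FALSE, seed = .subSeed(seed, 1)),
    pair_slight = sceneSpec(nCells = 2, seed = .subSeed(seed, 2)),
    pair_heavy = sceneSpec(nCells = 2, width = 672, height = 672,
                           seed = .subSeed(seed, 3)),
    mass_5 = sceneSpec(nCells = 5, width = 1152, height = 1152,
                       cytoAxes = c(90, 135), seed = .subSeed(seed, 4)),
    pair_blurred = sceneSpec(nCells = 2, blurSigma = 4,
                             seed = .subSeed(seed, 5)))
}
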