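# Independent oracles, deliberately written as plain loops so they share no
# code path with the implementation they check.

# Bilinear sampling, scalar loop version with border clamping.
oracleBilinear <- function(g, x, y) {
  H <- nrow(g); W <- ncol(g)
  x <- min(max(x, 0), W - 1); y <- min(max(y, 0), H - 1)
  x0 <- floor(x); y0 <- floor(y)
  x1 <- min(x0 + 1, W - 1); y1 <- min(y0 + 1, H - 1)
  fx <- x - x0; fy <- y - y0
  (1 - fy) * ((1 - fx) * g[y0 + 1, x0 + 1] + fx * g[y0 + 1, x1 + 1]) +
    fy * ((1 - fx) * g[y1 + 1, x0 + 1] + fx * g[y1 + 1, x1 + 1])
}

# Exhaustive weighted-argmax point correction over all 2r+1 candidates,
# including the gating test and the tie-break rules.
oracleCorrectPoint <- function(g, point, normal, r, h1, lambdaT) {
  offs <- -r:r
  w <- numeric(length(offs)); gv <- numeric(length(offs))
  for (j in seq_along(offs)) {
    w[j] <- exp(-(abs(offs[j]) / h1)^2 / 2) / sqrt(2 * pi) / h1
    gv[j] <- oracleBilinear(g, point[1] + offs[j] * normal[1],
                            point[2] + offs[j] * normal[2])
  }
  wg <- w * gv
  delta <- abs(max(wg) - min(wg)) - lambdaT * max(w)
  if (delta <= 0) return(point)
  best <- NULL
  for (j in order(abs(offs), offs)) {   # smallest |t| first, then negative
    if (wg[j] == max(wg)) { best <- j; break }
  }
  c(point[1] + offs[best] * normal[1], point[2] + offs[best] * normal[2])
}

# Brute-force minimizer of the weighted least-squares objective.
oracleWeightedFit <- function(x, y, targetX, h2) {
  kw <- exp(-((targetX - x) / h2)^2 / 2) / sqrt(2 * pi) / h2
  w <- kw / sum(kw)
  obj <- function(beta) sum(w * (y - beta[1] - beta[2] * x)^2)
  best <- NULL
  for (start in list(c(0, 0), c(mean(y), 0), c(0, 1))) {
    fit <- stats::optim(start, obj, method = "BFGS",
                        control = list(reltol = 1e-16, maxit = 2000))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  best$par
}

# Even-odd point-in-polygon by per-pixel crossing count (ray toward +x).
oracleInsidePolygon <- function(px, py, poly) {
  n <- nrow(poly)
  crossings <- 0L
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    y1 <- poly[i, 2]; y2 <- poly[j, 2]
    if ((y1 > py) != (y2 > py)) {
      xint <- poly[i, 1] + (py - y1) * (poly[j, 1] - poly[i, 1]) / (y2 - y1)
      if (xint > px) crossings <- crossings + 1L
    }
  }
  crossings %% 2L == 1L
}

# RMS of a normal truncated to [-cap, cap].
truncNormRMS <- function(sigma, cap) {
  a <- cap / sigma
  sigma * sqrt(1 - 2 * a * stats::dnorm(a) / (2 * stats::pnorm(a) - 1))
}

radialRMS <- function(contour, center, radius) {
  p <- contourPoints(contour)
  sqrt(mean((sqrt((p[, 1] - center[1])^2 + (p[, 2] - center[2])^2) -
               radius)^2))
}
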