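# Internal numeric helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Replicate-pad a matrix by `k` rows/cols on every side.
.padReplicate <- function(m, k) {
  ri <- c(rep(1L, k), seq_len(nrow(m)), rep(nrow(m), k))
  ci <- c(rep(1L, k), seq_len(ncol(m)), rep(ncol(m), k))
  m[ri, ci, drop = FALSE]
}

# Separable Gaussian smoothing, direct convolution, replicate boundary,
# kernel truncated at 3*sigma. Direct (non-FFT) summation keeps interior
# pixels bit-identical under integer shifts of the input.
.gaussSmooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  H <- nrow(m); W <- ncol(m)
  p <- .padReplicate(m, r)
  # convolve along x (columns)
  out <- matrix(0, H + 2L * r, W)
  for (t in -r:r)
    out <- out + k[t + r + 1L] * p[, (1L + r + t):(W + r + t), drop = FALSE]
  # convolve along y (rows)
  res <- matrix(0, H, W)
  for (t in -r:r)
    res <- res + k[t + r + 1L] * out[(1L + r + t):(H + r + t), , drop = FALSE]
  res
}

# Central-difference gradient with replicate boundary; returns list(gx, gy).
.centralGradient <- function(m) {
  H <- nrow(m); W <- ncol(m)
  p <- .padReplicate(m, 1L)
  gx <- (p[2:(H + 1), 3:(W + 2), drop = FALSE] -
         p[2:(H + 1), 1:W, drop = FALSE]) / 2
  gy <- (p[3:(H + 2), 2:(W + 1), drop = FALSE] -
         p[1:H, 2:(W + 1), drop = FALSE]) / 2
  list(gx = gx, gy = gy)
}

.rowNorms <- function(m) sqrt(rowSums(m * m))

# Circular index helper (1-based).
.wrap1 <- function(i, n) ((i - 1L) %% n) + 1L

# Shoelace signed area of a closed polygon (n x 2 matrix).
.polyArea <- function(p) {
  n <- nrow(p)
  if (n < 3) return(0)
  q <- p[c(2:n, 1), , drop = FALSE]
  sum(p[, 1] * q[, 2] - q[, 1] * p[, 2]) / 2
}

# Cumulative arc length of a polyline (closed: append first point).
.arcLength <- function(p, closed = TRUE) {
  q <- if (closed) rbind(p, p[1, , drop = FALSE]) else p
  d <- sqrt(rowSums(diff(q)^2))
  c(0, cumsum(d))
}

# Resample a polyline to n points uniformly spaced in arc length.
.resamplePolyline <- function(p, n, closed = TRUE) {
  s <- .arcLength(p, closed)
  q <- if (closed) rbind(p, p[1, , drop = FALSE]) else p
  L <- s[length(s)]
  if (L <= 0) return(matrix(rep(p[1, ], each = n), n, 2))
  targets <- if (closed) seq(0, L, length.out = n + 1)[-(n + 1)]
             else seq(0, L, length.out = n)
  cbind(stats::approx(s, q[, 1], xout = targets, ties = "ordered")$y,
        stats::approx(s, q[, 2], xout = targets, ties = "ordered")$y)
}

# Minimum distance from each row of `p` to the polyline through `q`
# (closed polygon by default). Vectorized over all point/segment pairs.
.pointsToPolyline <- function(p, q, closed = TRUE) {
  a <- q
  b <- if (closed) q[c(2:nrow(q), 1), , drop = FALSE]
       else q[-1, , drop = FALSE]
  if (!closed) a <- a[-nrow(a), , drop = FALSE]
  dx <- b[, 1] - a[, 1]; dy <- b[, 2] - a[, 2]
  len2 <- pmax(dx * dx + dy * dy, .Machine$double.eps)
  # t = ((p - a) . d) / |d|^2, clamped to [0, 1]; n_p x n_seg
  px <- outer(p[, 1], a[, 1], "-")
  py <- outer(p[, 2], a[, 2], "-")
  tt <- sweep(sweep(px, 2, dx, "*") + sweep(py, 2, dy, "*"), 2, len2, "/")
  tt <- pmin(pmax(tt, 0), 1)
  ex <- px - sweep(tt, 2, dx, "*")
  ey <- py - sweep(tt, 2, dy, "*")
  sqrt(apply(ex * ex + ey * ey, 1, min))
}

# Deterministic seed derivation for sub-streams, kept below 2^31.
.subSeed <- function(base, a, b = 0L) {
  as.integer((abs(as.numeric(base)) * 97 + a * 7919 + b * 131071) %%
               2147483629)
}
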