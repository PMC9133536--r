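# Point interpolation (PI) and local point smoothing (LPS).

#' Densify sparse runs of a closed contour
#'
#' For every circularly adjacent pair farther apart than `2 * gap`
#' (strictly), inserts the minimal number of evenly spaced collinear points
#' so the resulting spacings fall below `gap`. Pairs at or below `2 * gap`
#' are left untouched, so the contour-wide guarantee after interpolation is
#' spacing `<= 2 * gap`, with `< gap` on every densified pair. Original
#' points are retained in order as a subsequence of the output.
#'
#' @param contour a [Contour-class].
#' @param gap maximum allowed spacing, px.
#' @return densified [Contour-class].
#' @examples
#' c4 <- Contour(rbind(c(0, 0), c(5, 0), c(5, 5), c(0, 5)))
#' nPoints(interpolateContour(c4, gap = 1))   # 5 inserted per side
#' @export
interpolateContour <- function(contour, gap = 1) {
  if (gap <= 0) stop("gap must be > 0")
  p <- contourPoints(contour)
  n <- nrow(p)
  pieces <- vector("list", n)
  for (i in seq_len(n)) {
    a <- p[i, ]; b <- p[.wrap1(i + 1L, n), ]
    d <- sqrt(sum((b - a)^2))
    pieces[[i]] <- if (d > 2 * gap) {
      k <- floor(d / gap)          # minimal k with d/(k+1) < gap
      ts <- c(0, (1:k) / (k + 1))
      cbind(a[1] + ts * (b[1] - a[1]), a[2] + ts * (b[2] - a[2]))
    } else {
      matrix(a, 1, 2)
    }
  }
  Contour(do.call(rbind, pieces), label = contour@label,
          shapeType = contour@shapeType, meta = contour@meta)
}

#' Local coordinate frame of a point group
#'
#' The frame's origin is the group's first point and its x-axis passes
#' through the first and last points, so both endpoints have frame
#' ordinate 0. A degenerate chord (first = last) falls back to the group's
#' principal axis; if all points coincide the frame is undefined.
#'
#' @param group m x 2 matrix of points, m >= 2.
#' @return list with `origin` (length-2) and `angle` (radians); rotating
#'   by `-angle` about `origin` maps the group chord onto the +x axis.
#' @export
localFrame <- function(group) {
  group <- as.matrix(group)
  m <- nrow(group)
  if (m < 2) stop("a frame needs at least 2 points")
  v <- group[m, ] - group[1, ]
  if (sqrt(sum(v^2)) < 1e-9) {
    centered <- sweep(group, 2, colMeans(group))
    sv <- svd(centered)
    if (sv$d[1] < 1e-9)
      stop("all group points coincide: local frame undefined")
    v <- sv$v[, 1]
  }
  list(origin = as.numeric(group[1, ]), angle = atan2(v[2], v[1]))
}

#' Transform points into a local frame
#' @param frame from [localFrame()].
#' @param p length-2 point or n x 2 matrix.
#' @return same shape as `p`, in frame coordinates.
#' @export
frameToLocal <- function(frame, p) {
  one <- is.null(dim(p))
  if (one) p <- matrix(p, ncol = 2)
  ca <- cos(frame$angle); sa <- sin(frame$angle)
  dx <- p[, 1] - frame$origin[1]; dy <- p[, 2] - frame$origin[2]
  out <- cbind(ca * dx + sa * dy, -sa * dx + ca * dy)
  if (one) as.numeric(out) else out
}

#' Transform frame coordinates back to world coordinates
#' @inheritParams frameToLocal
#' @export
frameToWorld <- function(frame, p) {
  one <- is.null(dim(p))
  if (one) p <- matrix(p, ncol = 2)
  ca <- cos(frame$angle); sa <- sin(frame$angle)
  out <- cbind(frame$origin[1] + ca * p[, 1] - sa * p[, 2],
               frame$origin[2] + sa * p[, 1] + ca * p[, 2])
  if (one) as.numeric(out) else out
}

#' Normalized regression weights at a target abscissa
#'
#' `w_j(x) = K(|x - x_j|, h2) / sum_m K(|x - x_m|, h2)`; the weights sum to
#' one at every target.
#'
#' @param x abscissas of the group points (frame x-coordinates).
#' @param targetX target abscissa.
#' @param h2 bandwidth, px.
#' @return numeric weights summing to 1.
#' @export
regressionWeights <- function(x, targetX, h2) {
  w <- kernelWeight(abs(targetX - x), h2)
  s <- sum(w)
  if (s <= 0 || !is.finite(s)) {
    # kernel underflow far from target: fall back to nearest-point weight
    w <- as.numeric(abs(targetX - x) == min(abs(targetX - x)))
    s <- sum(w)
  }
  w / s
}

#' Weighted local linear fit in frame coordinates
#'
#' Solves the kernel-weighted least-squares line through the group points,
#' `beta = (X' w X)^{-1} X' w Y` with design `X = [1, x_j]` and weights
#' from [regressionWeights()]. The fitted ordinate at the target is
#' `beta0 + beta1 * targetX`.
#'
#' @param pointsInFrame m x 2 matrix `(x_j, y_j)`.
#' @param targetX target abscissa.
#' @param h2 bandwidth, px.
#' @return length-2 `c(beta0, beta1)`; errors with class
#'   `"llpcDegenerateFit"` when the weighted design is singular (all
#'   abscissas effectively equal), in which case callers leave the point
#'   unchanged.
#' @export
weightedLinearFit <- function(pointsInFrame, targetX, h2) {
  pointsInFrame <- as.matrix(pointsInFrame)
  if (nrow(pointsInFrame) < 2) stop("need at least 2 points to fit a line")
  x <- pointsInFrame[, 1]; y <- pointsInFrame[, 2]
  w <- regressionWeights(x, targetX, h2)
  X <- cbind(1, x)
  A <- crossprod(X, w * X)
  if (!is.finite(rcond(A)) || rcond(A) < 1e-12)
    stop(errorCondition("singular weighted design (all x equal)",
                        class = "llpcDegenerateFit"))
  as.numeric(solve(A, crossprod(X, w * y)))
}

.reducedGroupSize <- function(n, ng) {
  if (n >= ng) return(as.integer(ng))
  k <- as.integer(n)
  if (k %% 2L == 0L) k <- k - 1L   # largest odd value <= n
  max(k, 3L)
}

#' Smooth one contour point by local weighted linear regression
#'
#' Takes the circular window of `ng` consecutive points holding index `i`
#' at its center position (`rf = floor((ng - 1)/2)` points before, the rest
#' after), builds the local frame on the window endpoints, fits a weighted
#' line, and replaces only point `i`'s frame ordinate with the fitted
#' value. A degenerate fit leaves the point unchanged.
#'
#' @param contour a [Contour-class].
#' @param i point index (1-based).
#' @param ng group size (reduced to the largest odd value <= n when the
#'   contour is shorter).
#' @param h2 regression bandwidth; default `floor((ng - 1)/2)/2` after any
#'   reduction.
#' @return length-2 smoothed `(x, y)`.
#' @export
smoothPoint <- function(contour, i, ng = 14, h2 = NULL) {
  p <- contourPoints(contour)
  n <- nrow(p)
  ngEff <- .reducedGroupSize(n, ng)
  rf <- floor((ngEff - 1) / 2)
  if (is.null(h2)) h2 <- rf / 2
  idx <- .wrap1(i - rf + 0:(ngEff - 1L), n)
  group <- p[idx, , drop = FALSE]
  frame <- tryCatch(localFrame(group), error = function(e) NULL)
  if (is.null(frame)) return(p[i, ])
  loc <- frameToLocal(frame, group)
  tx <- loc[rf + 1L, 1]
  beta <- tryCatch(weightedLinearFit(loc, tx, h2),
                   llpcDegenerateFit = function(e) NULL)
  if (is.null(beta)) return(p[i, ])
  frameToWorld(frame, c(tx, beta[1] + beta[2] * tx))
}

#' Local point smoothing of a whole contour
#'
#' Applies [smoothPoint()] independently to every index, all windows drawn
#' from the input contour (parallel update), realizing the stride-1
#' per-point smoothing of the corrected discrete edge. Output length equals
#' input length. Contours shorter than `ng` use a reduced odd group size
#' with a warning.
#'
#' @inheritParams smoothPoint
#' @return smoothed [Contour-class].
#' @export
smoothContour <- function(contour, ng = 14, h2 = NULL) {
  p <- contourPoints(contour)
  n <- nrow(p)
  if (n < 3) stop("need at least 3 points")
  ngEff <- .reducedGroupSize(n, ng)
  if (ngEff < ng)
    warning(sprintf("contour has %d points < ng = %d; group size reduced to %d",
                    n, ng, ngEff))
  out <- p
  for (i in seq_len(n)) out[i, ] <- smoothPoint(contour, i, ngEff, h2)
  Contour(out, label = contour@label, shapeType = contour@shapeType,
          meta = contour@meta)
}
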