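# Gradient-guided point correction (GPC): snap each label point to the
# kernel-weighted gradient peak searched along the contour normal, gated by
# the gradient-variation test Delta.

#' Unit normals of a closed contour
#'
#' The normal at point i is perpendicular to the central chord
#' `p[i+1] - p[i-1]` (circular indexing). Its sign is arbitrary: candidate
#' searches span both sides. A zero central chord falls back to the forward
#' chord `p[i+1] - p[i]`; if that is also zero the contour is invalid.
#'
#' @param contour a [Contour-class] with at least 3 points.
#' @return n x 2 matrix of unit normals.
#' @export
contourNormals <- function(contour) {
  p <- contourPoints(contour)
  n <- nrow(p)
  if (n < 3) stop("need at least 3 points to estimate normals")
  nxt <- p[c(2:n, 1), , drop = FALSE]
  prv <- p[c(n, 1:(n - 1)), , drop = FALSE]
  chord <- nxt - prv
  bad <- .rowNorms(chord) < 1e-12
  if (any(bad)) chord[bad, ] <- (nxt - p)[bad, , drop = FALSE]
  nrm <- .rowNorms(chord)
  if (any(nrm < 1e-12))
    stop("degenerate contour: coincident neighbor points leave the normal undefined")
  cbind(-chord[, 2], chord[, 1]) / nrm
}

#' Gaussian kernel weight
#'
#' `K(x, h) = kappa(x/h) / h` with `kappa` the standard normal density, the
#' weighting kernel used both for gradient candidates and for the local
#' regression.
#'
#' @param distance nonnegative distance(s), px.
#' @param h bandwidth, px, > 0.
#' @return numeric weight(s).
#' @examples
#' kernelWeight(0, 7.5)          # 1 / (7.5 * sqrt(2 * pi))
#' @export
kernelWeight <- function(distance, h) {
  if (length(h) != 1 || h <= 0) stop("bandwidth h must be > 0")
  stats::dnorm(distance / h) / h
}

#' Build the candidate set for one label point
#'
#' Candidates sit at unit-spaced signed offsets `-r ... r` along the unit
#' normal through the point (2r + 1 candidates, offset 0 being the point
#' itself). Each carries the bilinearly sampled gradient value and the
#' kernel weight `K(|t|, h1)`.
#'
#' @param point length-2 `(x, y)`.
#' @param normal length-2 unit vector.
#' @param field a [GradientField-class].
#' @param r search radius, px.
#' @param h1 weight bandwidth, px; default `r/2`.
#' @return list with `center`, `offsets`, `points` (matrix), `weights`,
#'   `gvalues`.
#' @export
buildCandidates <- function(point, normal, field, r = 15, h1 = r / 2) {
  offsets <- -r:r
  pts <- cbind(point[1] + offsets * normal[1],
               point[2] + offsets * normal[2])
  list(center = as.numeric(point), offsets = offsets, points = pts,
       weights = kernelWeight(abs(offsets), h1),
       gvalues = sampleBilinear(field, pts))
}

#' Gradient-variation statistic of a candidate set
#'
#' `Delta = |max(w * g) - min(w * g)| - lambdaT * max(w)` over the
#' candidates. A point is considered to lie in a strong-gradient region,
#' and is moved, exactly when `Delta > 0`.
#'
#' @param cands candidate set from [buildCandidates()].
#' @param lambdaT gradient-variation threshold.
#' @return scalar Delta.
#' @export
gpcDelta <- function(cands, lambdaT = 4) {
  wg <- cands$weights * cands$gvalues
  abs(max(wg) - min(wg)) - lambdaT * max(cands$weights)
}

#' Correct one label point from its candidate set
#'
#' If `Delta > 0`, returns the candidate maximizing the weighted gradient
#' `w * g`; otherwise the original point, unchanged. Ties are broken toward
#' the smallest absolute offset, then toward the negative offset, so the
#' result is deterministic and displacement-minimal.
#'
#' @inheritParams gpcDelta
#' @return length-2 corrected `(x, y)`.
#' @export
correctPoint <- function(cands, lambdaT = 4) {
  if (gpcDelta(cands, lambdaT) <= 0) return(cands$center)
  wg <- cands$weights * cands$gvalues
  idx <- which(wg == max(wg))
  best <- idx[order(abs(cands$offsets[idx]), cands$offsets[idx])][1]
  as.numeric(cands$points[best, ])
}

#' Gradient-guided point correction of a whole contour
#'
#' Every point is corrected independently, with normals and candidate sets
#' built from the original input contour (parallel update, no sequential
#' dependence), so the result is order-independent and deterministic.
#' Output has the same length, order and label as the input, and no point
#' moves farther than `r` px.
#'
#' @param contour a [Contour-class].
#' @param field a [GradientField-class] of the annotated image.
#' @param r search radius, px.
#' @param lambdaT gradient-variation threshold.
#' @param h1 weight bandwidth, px; default `r/2`.
#' @return corrected [Contour-class].
#' @export
gpcContour <- function(contour, field, r = 15, lambdaT = 4, h1 = r / 2) {
  p <- contourPoints(contour)
  normals <- contourNormals(contour)
  out <- p
  for (i in seq_len(nrow(p))) {
    cands <- buildCandidates(p[i, ], normals[i, ], field, r = r, h1 = h1)
    out[i, ] <- correctPoint(cands, lambdaT)
  }
  Contour(out, label = contour@label, shapeType = contour@shapeType,
          meta = contour@meta)
}
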