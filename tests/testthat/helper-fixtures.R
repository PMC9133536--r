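# Geometry and image fixtures, built in code.

circleContour <- function(n = 64, radius = 20, center = c(32, 32),
                          label = "cytoplasm") {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  Contour(cbind(center[1] + radius * cos(t), center[2] + radius * sin(t)),
          label = label)
}

squareContour <- function(side = 10, origin = c(0, 0)) {
  Contour(rbind(origin,
                origin + c(side, 0),
                origin + c(side, side),
                origin + c(0, side)))
}

# Dense axis-aligned rectangle: vertices every `step` px along the sides.
denseRectContour <- function(x0, y0, x1, y1, step = 1) {
  xs <- seq(x0, x1, by = step); ys <- seq(y0, y1, by = step)
  pts <- rbind(cbind(xs[-length(xs)], y0),
               cbind(x1, ys[-length(ys)]),
               cbind(rev(xs)[-length(xs)], y1),
               cbind(x0, rev(ys)[-length(ys)]))
  Contour(pts)
}

stepImage <- function(H = 32, W = 32, at = W %/% 2, lo = 0, hi = 255) {
  m <- matrix(lo, H, W)
  m[, (at + 1):W] <- hi
  m
}

diskImage <- function(H = 96, W = 96, center = c(48, 48), radius = 28,
                      lo = 30, hi = 150) {
  X <- matrix(rep(0:(W - 1), each = H), H, W)
  Y <- matrix(rep(0:(H - 1), times = W), H, W)
  m <- matrix(lo, H, W)
  m[(X - center[1])^2 + (Y - center[2])^2 <= radius^2] <- hi
  m
}

flatField <- function(H = 40, W = 40) {
  gaussianGradient(matrix(7, H, W), sigma = 2)
}

randomField <- function(H = 24, W = 24, integerValued = FALSE) {
  v <- if (integerValued) sample(0:5, H * W, replace = TRUE) * 51
       else stats::runif(H * W, 0, 200)
  gaussianGradient(matrix(v, H, W), sigma = 2)
}

smallSceneSpec <- function(seed = 5, nCells = 1) {
  sceneSpec(width = 320, height = 320, nCells = nCells,
            cytoAxes = c(70, 100), overlap = FALSE, seed = seed)
}

tinyAnnotation <- function() {
  sq <- Contour(rbind(c(2, 2), c(20, 2), c(20, 20), c(2, 20)),
                label = "cytoplasm", meta = list(group_id = 7))
  tri <- Contour(rbind(c(30, 5.25), c(44.5, 8), c(35, 19)),
                 label = "细胞质")
  annotationDocument(list(sq, tri), imageHeight = 48, imageWidth = 64,
                     imagePath = "img.png",
                     meta = list(version = "5.0.1", flags = list()))
}
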