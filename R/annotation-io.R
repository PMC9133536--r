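# labelme-dialect annotation I/O, edge/mask rasterization, and the
# overlapping-grid dataset patch cutter.

.KNOWN_DOC_FIELDS <- c("imagePath", "imageHeight", "imageWidth", "shapes")
.KNOWN_SHAPE_FIELDS <- c("label", "points", "shape_type")

#' Read a labelme-dialect annotation file
#'
#' Parses the `shapes` list of labeled polygons. Duplicate consecutive
#' points are dropped, a closing point equal to the first is removed
#' (closure is implicit), and coordinates are clamped to
#' `[0, W] x [0, H]` with a warning. Non-polygon shapes are kept but
#' flagged in their `meta`. Unknown fields, at document and shape level,
#' are preserved verbatim for round-trip.
#'
#' @param path annotation file.
#' @return An [AnnotationDocument-class].
#' @export
readAnnotation <- function(path) {
  raw <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    stop(sprintf("cannot parse annotation '%s': %s",
                                 path, conditionMessage(e))))
  H <- raw$imageHeight; W <- raw$imageWidth
  if (is.null(H) || is.null(W))
    stop(sprintf("annotation '%s' lacks imageHeight/imageWidth", path))
  shapes <- lapply(seq_along(raw$shapes), function(k) {
    sh <- raw$shapes[[k]]
    pts <- tryCatch(
      do.call(rbind, lapply(sh$points, function(q) as.numeric(q[1:2]))),
      error = function(e) NULL)
    if (is.null(pts) || any(!is.finite(pts)))
      stop(sprintf("malformed points in '%s', shape %d", path, k))
    # closure dedup, then consecutive dedup
    n <- nrow(pts)
    if (n > 1 && all(pts[n, ] == pts[1, ])) pts <- pts[-n, , drop = FALSE]
    if (nrow(pts) > 1) {
      keep <- c(TRUE, rowSums(abs(diff(pts))) > 0)
      pts <- pts[keep, , drop = FALSE]
    }
    cl <- cbind(pmin(pmax(pts[, 1], 0), W), pmin(pmax(pts[, 2], 0), H))
    if (any(cl != pts))
      warning(sprintf("shape %d of '%s': %d point(s) clamped into [0,%d]x[0,%d]",
                      k, path, sum(rowSums(cl != pts) > 0), W, H))
    type <- sh$shape_type %||% "polygon"
    meta <- sh[setdiff(names(sh), .KNOWN_SHAPE_FIELDS)]
    if (type != "polygon") meta$flagged_non_polygon <- TRUE
    if (type == "polygon" && nrow(cl) < 3)
      stop(sprintf("shape %d of '%s': polygon with fewer than 3 distinct points",
                   k, path))
    Contour(cl, label = sh$label %||% "", shapeType = type, meta = meta)
  })
  annotationDocument(shapes, imageHeight = H, imageWidth = W,
                     imagePath = raw$imagePath %||% "",
                     meta = raw[setdiff(names(raw), .KNOWN_DOC_FIELDS)])
}

#' Write an annotation document in the labelme dialect
#'
#' Float coordinates are written at full precision, so a write/read cycle
#' reproduces the document (coordinates to better than 1e-9). Preserved
#' unknown fields are emitted alongside the standard keys.
#'
#' @param doc an [AnnotationDocument-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeAnnotation <- function(doc, path) {
  shapes <- lapply(doc@shapes, function(sh) {
    meta <- sh@meta
    meta$flagged_non_polygon <- NULL
    c(list(label = sh@label,
           points = lapply(seq_len(nrow(sh@points)),
                           function(i) as.numeric(sh@points[i, ])),
           shape_type = sh@shapeType),
      meta)
  })
  out <- c(list(imagePath = doc@imagePath,
                imageHeight = doc@imageHeight,
                imageWidth = doc@imageWidth,
                shapes = shapes),
           doc@meta)
  txt <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                          null = "null")
  writeLines(txt, path, useBytes = TRUE)
  invisible(path)
}

# Integer line rasterization between two pixel coordinates (inclusive).
.linePixels <- function(x0, y0, x1, y1) {
  n <- max(abs(x1 - x0), abs(y1 - y0))
  if (n == 0) return(cbind(x0, y0))
  t <- 0:n
  cbind(round(x0 + t * (x1 - x0) / n), round(y0 + t * (y1 - y0) / n))
}

#' Rasterize annotation polygons as a binary edge map
#'
#' Each polygon is drawn as a closed 1-px polyline (integer line
#' rasterization between consecutive rounded points, no anti-aliasing);
#' overlapping polygons draw over each other, giving the union of edges.
#' Background 0, edge 255.
#'
#' @param doc an [AnnotationDocument-class].
#' @return H x W integer matrix with values 0/255.
#' @export
rasterizeEdges <- function(doc) {
  H <- as.integer(doc@imageHeight); W <- as.integer(doc@imageWidth)
  m <- matrix(0L, H, W)
  for (sh in doc@shapes) {
    if (sh@shapeType != "polygon") next
    v <- round(sh@points)
    v[, 1] <- pmin(pmax(v[, 1], 0), W - 1)
    v[, 2] <- pmin(pmax(v[, 2], 0), H - 1)
    n <- nrow(v)
    for (i in seq_len(n)) {
      j <- .wrap1(i + 1L, n)
      px <- .linePixels(v[i, 1], v[i, 2], v[j, 1], v[j, 2])
      m[cbind(px[, 2] + 1L, px[, 1] + 1L)] <- 255L
    }
  }
  m
}

# Even-odd scanline fill at integer pixel centers. A crossing exactly at a
# pixel-center abscissa counts as "not to the right" (half-open rule).
.fillPolygonEvenOdd <- function(pts, H, W) {
  m <- matrix(0L, H, W)
  n <- nrow(pts)
  x1 <- pts[, 1]; y1 <- pts[, 2]
  x2 <- pts[c(2:n, 1), 1]; y2 <- pts[c(2:n, 1), 2]
  for (yr in seq_len(H) - 1L) {
    crosses <- (y1 > yr) != (y2 > yr)
    if (!any(crosses)) next
    xi <- x1[crosses] + (yr - y1[crosses]) *
      (x2[crosses] - x1[crosses]) / (y2[crosses] - y1[crosses])
    xi <- sort(xi)
    cntLeft <- findInterval(0:(W - 1), xi)       # crossings <= pixel center
    inside <- (length(xi) - cntLeft) %% 2L == 1L # odd count strictly right
    m[yr + 1L, inside] <- 255L
  }
  m
}

# TRUE when any two non-adjacent polygon edges properly intersect.
.selfIntersects <- function(pts) {
  n <- nrow(pts)
  if (n < 4) return(FALSE)
  a <- pts; b <- pts[c(2:n, 1), , drop = FALSE]
  cross <- function(ox, oy, px, py, qx, qy)
    (px - ox) * (qy - oy) - (py - oy) * (qx - ox)
  hit <- FALSE
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    js <- js[!(i == 1L & js == n)]      # skip edges sharing a vertex
    if (!length(js)) next
    d1 <- cross(a[i, 1], a[i, 2], b[i, 1], b[i, 2], a[js, 1], a[js, 2])
    d2 <- cross(a[i, 1], a[i, 2], b[i, 1], b[i, 2], b[js, 1], b[js, 2])
    d3 <- cross(a[js, 1], a[js, 2], b[js, 1], b[js, 2],
                rep(a[i, 1], length(js)), rep(a[i, 2], length(js)))
    d4 <- cross(a[js, 1], a[js, 2], b[js, 1], b[js, 2],
                rep(b[i, 1], length(js)), rep(b[i, 2], length(js)))
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) { hit <- TRUE; break }
  }
  hit
}

#' Rasterize annotation polygons as per-instance binary masks
#'
#' One filled mask per polygon shape (even-odd fill at integer pixel
#' centers), instances kept separate so overlapping cells remain
#' representable. Self-intersecting polygons are filled by the even-odd
#' rule and reported with a warning.
#'
#' @param doc an [AnnotationDocument-class].
#' @return list of H x W integer matrices (0/255), one per polygon shape.
#' @export
rasterizeMasks <- function(doc) {
  H <- as.integer(doc@imageHeight); W <- as.integer(doc@imageWidth)
  polys <- Filter(function(s) s@shapeType == "polygon", doc@shapes)
  lapply(seq_along(polys), function(k) {
    pts <- polys[[k]]@points
    if (.selfIntersects(pts))
      warning(sprintf("shape %d ('%s') self-intersects; even-odd fill applied",
                      k, polys[[k]]@label))
    .fillPolygonEvenOdd(pts, H, W)
  })
}

#' Overlapping cutting grid for dataset patch extraction
#'
#' For an image of W x H px cut into patches of `patchW x patchH`
#' (`a = W/patchW` and `b = H/patchH` must be integers), returns the base
#' `a x b` grid plus the grids shifted right by `patchW/2`, down by
#' `patchH/2`, and both — `(2a - 1)(2b - 1)` half-open windows in total,
#' every one fully inside the image, so every boundary region of the base
#' grid appears intact inside some shifted window.
#'
#' @param W,H image size, px.
#' @param patchW,patchH patch size, px.
#' @return list of class `PatchGrid` with `patchW`, `patchH`, `offsets`
#'   (grid shifts) and `windows` (n x 4 matrix `x0, y0, x1, y1`, half-open).
#' @examples
#' nrow(buildPatchGrid(2048, 1536, 512, 384)$windows)  # 49
#' @export
buildPatchGrid <- function(W, H, patchW, patchH) {
  if (W %% patchW != 0 || H %% patchH != 0)
    stop("patch size must divide the image size exactly (no partial patches)")
  a <- W %/% patchW; b <- H %/% patchH
  sx <- patchW %/% 2L; sy <- patchH %/% 2L
  gridFor <- function(dx, dy, nx, ny) {
    if (nx < 1 || ny < 1) return(NULL)
    x0 <- dx + patchW * (seq_len(nx) - 1L)
    y0 <- dy + patchH * (seq_len(ny) - 1L)
    cbind(rep(x0, times = ny), rep(y0, each = nx))
  }
  tl <- rbind(gridFor(0L, 0L, a, b),
              gridFor(sx, 0L, a - 1L, b),
              gridFor(0L, sy, a, b - 1L),
              gridFor(sx, sy, a - 1L, b - 1L))
  windows <- cbind(tl, tl[, 1] + patchW, tl[, 2] + patchH)
  colnames(windows) <- c("x0", "y0", "x1", "y1")
  structure(list(patchW = patchW, patchH = patchH,
                 offsets = rbind(c(0, 0), c(sx, 0), c(0, sy), c(sx, sy)),
                 windows = windows),
            class = "PatchGrid")
}

# Sutherland-Hodgman clip of a polygon against the rectangle
# [x0,x1] x [y0,y1]; returns an m x 2 matrix (possibly < 3 rows).
.clipPolygonRect <- function(pts, x0, y0, x1, y1) {
  clipHalf <- function(p, inside, intersect) {
    n <- nrow(p)
    if (n == 0) return(p)
    out <- vector("list", n)
    for (i in seq_len(n)) {
      a <- p[i, ]; b <- p[.wrap1(i + 1L, n), ]
      ia <- inside(a); ib <- inside(b)
      out[[i]] <-
        if (ia && ib) matrix(b, 1, 2)
        else if (ia && !ib) matrix(intersect(a, b), 1, 2)
        else if (!ia && ib) rbind(intersect(a, b), b)
        else matrix(numeric(0), 0, 2)
    }
    res <- do.call(rbind, out)
    if (nrow(res) > 1) {
      keep <- c(TRUE, .rowNorms(diff(res)) > 1e-9)
      res <- res[keep, , drop = FALSE]
      if (nrow(res) > 1 &&
          sqrt(sum((res[1, ] - res[nrow(res), ])^2)) < 1e-9)
        res <- res[-nrow(res), , drop = FALSE]
    }
    res
  }
  ix <- function(a, b, t) a + t * (b - a)
  p <- pts
  p <- clipHalf(p, function(q) q[1] >= x0,
                function(a, b) ix(a, b, (x0 - a[1]) / (b[1] - a[1])))
  p <- clipHalf(p, function(q) q[1] <= x1,
                function(a, b) ix(a, b, (x1 - a[1]) / (b[1] - a[1])))
  p <- clipHalf(p, function(q) q[2] >= y0,
                function(a, b) ix(a, b, (y0 - a[2]) / (b[2] - a[2])))
  p <- clipHalf(p, function(q) q[2] <= y1,
                function(a, b) ix(a, b, (y1 - a[2]) / (b[2] - a[2])))
  p
}

#' Cut an image and its annotations into grid patches
#'
#' Per window: pixels are cropped bit-exactly and every polygon is clipped
#' geometrically to the window rectangle, re-expressed in window-local
#' coordinates; shapes with empty intersection are dropped. Non-polygon
#' shapes are kept only when fully inside the window.
#'
#' @param image H x W intensity matrix.
#' @param doc matching [AnnotationDocument-class].
#' @param grid a `PatchGrid` from [buildPatchGrid()].
#' @return list of `list(image=, document=)`, one per window, in window
#'   order.
#' @export
cutImageAndLabels <- function(image, doc, grid) {
  image <- toGrayscale(image)
  if (nrow(image) != doc@imageHeight || ncol(image) != doc@imageWidth)
    stop("image size does not match annotation document")
  apply_window <- function(wi) {
    w <- grid$windows[wi, ]
    patch <- image[(w["y0"] + 1):w["y1"], (w["x0"] + 1):w["x1"],
                   drop = FALSE]
    shapes <- list()
    for (sh in doc@shapes) {
      if (sh@shapeType == "polygon") {
        cp <- .clipPolygonRect(sh@points, w["x0"], w["y0"], w["x1"], w["y1"])
        if (nrow(cp) >= 3 && abs(.polyArea(cp)) > 1e-9) {
          cp <- sweep(cp, 2, c(w["x0"], w["y0"]))
          shapes[[length(shapes) + 1L]] <-
            Contour(cp, label = sh@label, shapeType = "polygon",
                    meta = sh@meta)
        }
      } else {
        p <- sh@points
        if (all(p[, 1] >= w["x0"] & p[, 1] <= w["x1"] &
                p[, 2] >= w["y0"] & p[, 2] <= w["y1"]))
          shapes[[length(shapes) + 1L]] <-
            Contour(sweep(p, 2, c(w["x0"], w["y0"])), label = sh@label,
                    shapeType = sh@shapeType, meta = sh@meta)
      }
    }
    doc2 <- annotationDocument(shapes, imageHeight = grid$patchH,
                               imageWidth = grid$patchW,
                               imagePath = doc@imagePath)
    list(image = patch, document = doc2)
  }
  lapply(seq_len(nrow(grid$windows)), apply_window)
}
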