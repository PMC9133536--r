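test_that("annotation write/read round-trips documents exactly", {
  doc <- tinyAnnotation()
  path <- withr::local_tempfile(fileext = ".json")
  writeAnnotation(doc, path)
  back <- readAnnotation(path)
  expect_identical(back@imageHeight, 48)
  expect_identical(back@imageWidth, 64)
  expect_identical(back@imagePath, "img.png")
  expect_length(shapes(back), 2)
  for (i in 1:2) {
    expect_equal(contourPoints(shapes(back)[[i]]),
                 contourPoints(shapes(doc)[[i]]), tolerance = 1e-9)
    expect_identical(contourLabel(shapes(back)[[i]]),
                     contourLabel(shapes(doc)[[i]]))
  }
  # unicode label and unknown fields survive
  expect_identical(contourLabel(shapes(back)[[2]]), "细胞质")
  expect_equal(shapes(back)[[1]]@meta$group_id, 7)
  expect_identical(back@meta$version, "5.0.1")
  # a second write is byte-identical (full-precision floats)
  path2 <- withr::local_tempfile(fileext = ".json")
  writeAnnotation(back, path2)
  expect_identical(readLines(path), readLines(path2))

  emptyPath <- withr::local_tempfile(fileext = ".json")
  writeAnnotation(annotationDocument(list(), 10, 10), emptyPath)
  expect_length(shapes(readAnnotation(emptyPath)), 0)
})

test_that("reading drops closure duplicates and clamps out-of-range points", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(list(
    imagePath = "x.png", imageHeight = 100, imageWidth = 100,
    shapes = list(
      list(label = "cytoplasm", shape_type = "polygon",
           points = list(c(0, 0), c(10, 0), c(10, 0), c(10, 10), c(0, 10),
                         c(0, 0))),
      list(label = "nucleus", shape_type = "polygon",
           points = list(c(-2, 5), c(8, 5), c(4, 120))))),
    auto_unbox = TRUE), path)
  expect_warning(doc <- readAnnotation(path), "clamped")
  expect_identical(nPoints(shapes(doc)[[1]]), 4L)
  p2 <- contourPoints(shapes(doc)[[2]])
  expect_equal(p2[1, ], c(0, 5))
  expect_equal(p2[3, ], c(4, 100))
  expect_error(readAnnotation(withr::local_tempfile(lines = "{nope",
                                                    fileext = ".json")),
               "cannot parse")
})

test_that("edge rasterization draws 1-px closed perimeters", {
  w <- 12L; h <- 7L
  rect <- Contour(rbind(c(3, 2), c(3 + w - 1, 2), c(3 + w - 1, 2 + h - 1),
                        c(3, 2 + h - 1)))
  doc <- annotationDocument(list(rect), imageHeight = 20, imageWidth = 30)
  m <- rasterizeEdges(doc)
  expect_identical(dim(m), c(20L, 30L))
  expect_identical(sum(m == 255L), 2L * (w + h) - 4L)
  expect_true(all(m %in% c(0L, 255L)))
  # empty document: all zero
  expect_true(all(rasterizeEdges(annotationDocument(list(), 20, 30)) == 0L))
  # drawing the same polygon twice changes nothing (union of edges)
  doc2 <- annotationDocument(list(rect, rect), imageHeight = 20,
                             imageWidth = 30)
  expect_identical(rasterizeEdges(doc2), m)
  # union of per-shape rasters equals the multi-shape raster
  tri <- Contour(rbind(c(20, 3), c(28, 10), c(16, 14)))
  both <- annotationDocument(list(rect, tri), 20, 30)
  sep <- pmax(rasterizeEdges(annotationDocument(list(rect), 20, 30)),
              rasterizeEdges(annotationDocument(list(tri), 20, 30)))
  expect_identical(rasterizeEdges(both), sep)
})

test_that("mask rasterization matches a pixel-center point-in-polygon oracle", {
  sq <- Contour(rbind(c(2.5, 3.5), c(12.5, 3.5), c(12.5, 13.5), c(2.5, 13.5)))
  tri <- Contour(rbind(c(6, 2), c(17, 9), c(4, 16)))
  doc <- annotationDocument(list(sq, tri), imageHeight = 18, imageWidth = 20)
  masks <- rasterizeMasks(doc)
  expect_length(masks, 2)
  for (k in 1:2) {
    poly <- contourPoints(shapes(doc)[[k]])
    ref <- matrix(0L, 18, 20)
    for (yy in 0:17) for (xx in 0:19)
      if (oracleInsidePolygon(xx, yy, poly)) ref[yy + 1, xx + 1] <- 255L
    expect_identical(masks[[k]], ref)
  }
  # the 10x10 square at half-integer corners covers exactly 100 centers
  expect_identical(sum(masks[[1]] == 255L), 100L)
  # overlapping instances stay separate and intersect
  expect_gt(sum(masks[[1]] == 255L & masks[[2]] == 255L), 0)
  expect_length(rasterizeMasks(annotationDocument(list(), 5, 5)), 0)
  # self-intersecting bow-tie is filled even-odd, with a warning
  bow <- Contour(rbind(c(1, 1), c(10, 10), c(10, 1), c(1, 10)))
  expect_warning(mb <- rasterizeMasks(annotationDocument(list(bow), 12, 12)),
                 "self-intersects")
  expect_identical(mb[[1]][3, 6], 0L)   # region above the crossing is outside
})

test_that("patch grids enumerate (2a-1)(2b-1) interior windows", {
  g <- buildPatchGrid(2048, 1536, 512, 384)
  expect_identical(nrow(g$windows), 49L)
  expect_identical(nrow(buildPatchGrid(512, 384, 512, 384)$windows), 1L)
  expect_identical(nrow(buildPatchGrid(1024, 768, 512, 384)$windows), 9L)
  for (a in 1:4) for (b in 1:4) {
    gg <- buildPatchGrid(10 * a, 8 * b, 10, 8)
    w <- gg$windows
    expect_identical(nrow(w), (2L * a - 1L) * (2L * b - 1L))
    expect_identical(nrow(unique(w)), nrow(w))
    expect_true(all(w[, "x0"] >= 0 & w[, "y0"] >= 0 &
                      w[, "x1"] <= 10 * a & w[, "y1"] <= 8 * b))
    expect_true(all(w[, "x1"] - w[, "x0"] == 10))
  }
  expect_error(buildPatchGrid(100, 80, 30, 40), "divide")
})

test_that("cutting crops pixels bit-exactly and clips polygons to windows", {
  set.seed(55)
  img <- matrix(runif(64 * 48, 0, 255), 48, 64)
  sq <- Contour(rbind(c(10, 10), c(22, 10), c(22, 20), c(10, 20)),
                label = "cytoplasm")
  span <- Contour(rbind(c(24, 6), c(40, 6), c(40, 18), c(24, 18)),
                  label = "nucleus")
  doc <- annotationDocument(list(sq, span), imageHeight = 48, imageWidth = 64)
  grid <- buildPatchGrid(64, 48, 32, 24)
  patches <- cutImageAndLabels(img, doc, grid)
  expect_length(patches, 9)
  for (i in seq_along(patches)) {
    w <- grid$windows[i, ]
    expect_identical(patches[[i]]$image,
                     img[(w["y0"] + 1):w["y1"], (w["x0"] + 1):w["x1"]])
    for (sh in shapes(patches[[i]]$document)) {
      p <- contourPoints(sh)
      expect_true(all(p[, 1] >= -1e-9 & p[, 1] <= 32 + 1e-9 &
                        p[, 2] >= -1e-9 & p[, 2] <= 24 + 1e-9))
    }
  }
  # a polygon fully inside the first window appears there translated
  p1 <- shapes(patches[[1]]$document)
  expect_identical(contourPoints(p1[[1]]), contourPoints(sq))
  # the spanning polygon is clipped at the window edge x = 32
  clipped <- shapes(patches[[1]]$document)[[2]]
  expect_equal(max(contourPoints(clipped)[, 1]), 32)
  expect_equal(llpc:::.polyArea(contourPoints(clipped)),
               llpc:::.polyArea(rbind(c(24, 6), c(32, 6), c(32, 18),
                                      c(24, 18))))
})

test_that("every base-grid seam is interior to some shifted window", {
  grid <- buildPatchGrid(128, 96, 32, 24)
  seamsX <- c(32, 64, 96)
  interior <- function(x0, x1, x) x > x0 & x < x1
  for (sx in seamsX) {
    w <- grid$windows
    expect_true(any(interior(w[, "x0"], w[, "x1"], sx) &
                      w[, "x1"] - w[, "x0"] == 32))
  }
})
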