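test_that("interpolation inserts the minimal even spacing per sparse pair", {
  # distance 5, gap 1: 5 inserted, spacing 5/6
  seg <- Contour(rbind(c(0, 0), c(5, 0), c(5, 5)))
  out <- contourPoints(interpolateContour(seg, gap = 1))
  onEdge <- out[out[, 2] == 0, , drop = FALSE]
  expect_identical(nrow(onEdge), 7L)
  expect_equal(diff(onEdge[, 1]), rep(5 / 6, 6), tolerance = 1e-12)

  # distance exactly 2*gap: untouched (strict inequality)
  pair <- Contour(rbind(c(0, 0), c(2, 0), c(1, 3)))
  out2 <- contourPoints(interpolateContour(pair, gap = 1))
  # the base pair at distance 2 is untouched; each sqrt(10) side gets 3
  expect_identical(nrow(out2), 9L)
  expect_true(any(out2[, 1] == 2 & out2[, 2] == 0))
  expect_identical(sum(out2[, 2] == 0), 2L)

  # distance 2.5, gap 1: 2 inserted, spacing 2.5/3
  tri <- Contour(rbind(c(0, 0), c(2.5, 0), c(1.25, 2)))
  out3 <- contourPoints(interpolateContour(tri, gap = 1))
  expect_identical(sum(out3[, 2] == 0), 4L)
})

test_that("after interpolation originals survive and spacings obey the bound", {
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(5:12, 1)
    pts <- cbind(runif(n, 0, 60), runif(n, 0, 60))
    ct <- Contour(pts)
    gap <- sample(c(0.5, 1, 2), 1)
    out <- contourPoints(interpolateContour(ct, gap = gap))
    # originals appear in order as a subsequence
    idx <- integer(n); k <- 1L
    for (i in seq_len(nrow(out))) {
      if (k <= n && all(out[i, ] == pts[k, ])) { idx[k] <- i; k <- k + 1L }
    }
    expect_identical(k, n + 1L)
    # circular spacings never exceed 2*gap; densified pairs are < gap
    sp <- sqrt(rowSums((out[c(2:nrow(out), 1), ] - out)^2))
    expect_true(all(sp <= 2 * gap + 1e-9))
    d0 <- sqrt(rowSums((pts[c(2:n, 1), ] - pts)^2))
    if (all(d0 > 2 * gap))
      expect_true(all(sp < gap))
    # orientation (signed area sign) is preserved
    expect_identical(sign(llpc:::.polyArea(out)), sign(llpc:::.polyArea(pts)))
  }
})

test_that("local frames put both endpoints on the x-axis", {
  # group already on the x-axis: identity frame
  g0 <- cbind(0:5, rep(0, 6))
  fr0 <- localFrame(g0)
  expect_equal(fr0$origin, c(0, 0))
  expect_equal(fr0$angle, 0)

  # rotating a group rotates the frame angle with it
  set.seed(3)
  base <- cbind(seq(0, 10, length.out = 8), rnorm(8))
  th <- 30 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  rot <- t(R %*% t(base))
  frA <- localFrame(base); frB <- localFrame(rot)
  locA <- frameToLocal(frA, base); locB <- frameToLocal(frB, rot)
  expect_equal(locA, locB, tolerance = 1e-9)

  # defining property: first and last map to y = 0
  for (rep in 1:20) {
    g <- cbind(runif(7, -40, 40), runif(7, -40, 40))
    if (sqrt(sum((g[7, ] - g[1, ])^2)) < 1e-6) next
    loc <- frameToLocal(localFrame(g), g)
    expect_lt(abs(loc[1, 2]), 1e-9)
    expect_lt(abs(loc[7, 2]), 1e-9)
  }

  # round trip through the frame is exact
  g <- cbind(runif(9, -5, 5), runif(9, -5, 5))
  fr <- localFrame(g)
  expect_equal(frameToWorld(fr, frameToLocal(fr, g)), g, tolerance = 1e-12)
})

test_that("degenerate chords fall back to the principal axis", {
  # first = last, spread along y
  g <- rbind(c(0, 0), c(1, 3), c(-1, 6), c(0.5, 9), c(0, 0))
  fr <- localFrame(g)
  axis <- c(cos(fr$angle), sin(fr$angle))
  expect_gt(abs(axis[2]), 0.9)
  expect_error(localFrame(matrix(2, 4, 2)), "coincide")
})

test_that("weighted linear fit is exact on lines and its weights normalize", {
  x <- c(-3, -1, 0, 2, 5)
  pts <- cbind(x, 2 * x + 1)
  for (tx in c(-2, 0, 3.7))
    expect_equal(weightedLinearFit(pts, tx, h2 = 2), c(1, 2),
                 tolerance = 1e-9)
  for (tx in c(-5, 0, 1.3, 10))
    expect_equal(sum(regressionWeights(x, tx, 3)), 1, tolerance = 1e-12)
  expect_error(weightedLinearFit(cbind(c(1, 1, 1), c(0, 1, 2)), 1, 2),
               class = "llpcDegenerateFit")
})

test_that("closed-form fit matches a brute-force minimizer on random instances", {
  set.seed(77)
  worst <- 0
  for (rep in 1:120) {
    m <- sample(5:14, 1)
    x <- sort(runif(m, -7, 7))
    y <- runif(1, -2, 2) + runif(1, -1.5, 1.5) * x + rnorm(m, 0, 0.7)
    tx <- runif(1, min(x), max(x))
    h2 <- runif(1, 1, 5)
    beta <- weightedLinearFit(cbind(x, y), tx, h2)
    ref <- oracleWeightedFit(x, y, tx, h2)
    worst <- max(worst, max(abs(beta - ref)))
  }
  expect_lt(worst, 1e-6)
})

test_that("smoothing leaves collinear windows fixed and damps outliers", {
  # long straight dense run: interior points are fixed points
  line <- Contour(rbind(cbind(seq(0, 40), 0), cbind(seq(40, 0), 15)))
  sm <- smoothContour(line, ng = 14)
  mid <- 10:30
  expect_equal(contourPoints(sm)[mid, ], contourPoints(line)[mid, ],
               tolerance = 1e-9)

  # a single 3-px outlier on a straight densified segment moves toward it
  pts <- cbind(seq(0, 40), 0)
  pts[21, 2] <- 3
  closed <- rbind(pts, cbind(seq(40, 0), 20))
  ct <- Contour(closed)
  out <- smoothPoint(ct, 21, ng = 14)
  expect_lt(abs(out[2]), 3)
  expect_gt(abs(out[2]), 0)
})

test_that("circular windows wrap consistently across the index origin", {
  set.seed(15)
  circ <- circleContour(n = 60, radius = 22, center = c(0, 0))
  p <- contourPoints(circ)
  jit <- p + matrix(rnorm(120, 0, 0.4), ncol = 2)
  ctA <- Contour(jit)
  shift <- 17L
  ctB <- Contour(jit[c((shift + 1):60, 1:shift), ])
  smA <- contourPoints(smoothContour(ctA, ng = 14))
  smB <- contourPoints(smoothContour(ctB, ng = 14))
  expect_equal(smB, smA[c((shift + 1):60, 1:shift), ], tolerance = 1e-9)
})

test_that("smoothing a jittered dense circle reduces radial error and contracts", {
  set.seed(31)
  n <- 240
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  r0 <- 40
  noisy <- Contour(cbind((r0 + rnorm(n, 0, 1)) * cos(t),
                         (r0 + rnorm(n, 0, 1)) * sin(t)))
  s1 <- smoothContour(noisy, ng = 14)
  expect_lt(radialRMS(s1, c(0, 0), r0), radialRMS(noisy, c(0, 0), r0))
  # second pass moves points less than the first (contraction)
  s2 <- smoothContour(s1, ng = 14)
  d1 <- mean(sqrt(rowSums((contourPoints(s1) - contourPoints(noisy))^2)))
  d2 <- mean(sqrt(rowSums((contourPoints(s2) - contourPoints(s1))^2)))
  expect_lt(d2, d1)
})

test_that("smoothing commutes with rigid motions", {
  set.seed(8)
  circ <- circleContour(n = 80, radius = 25, center = c(0, 0))
  jit <- contourPoints(circ) + matrix(rnorm(160, 0, 0.5), ncol = 2)
  ct <- Contour(jit)
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  shift <- c(12, -4)
  moved <- Contour(sweep(t(R %*% t(jit)), 2, -shift))
  smThenMove <- sweep(t(R %*% t(contourPoints(smoothContour(ct, 14)))), 2, -shift)
  moveThenSm <- contourPoints(smoothContour(moved, 14))
  expect_equal(moveThenSm, smThenMove, tolerance = 1e-6)
})

test_that("short contours reduce the group size with a warning", {
  tri <- Contour(rbind(c(0, 0), c(10, 0), c(5, 8)))
  expect_warning(out <- smoothContour(tri, ng = 14), "reduced")
  expect_identical(nPoints(out), 3L)
})
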