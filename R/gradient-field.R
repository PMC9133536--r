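#' Convert a multi-channel raster to a single-channel intensity image
#'
#' 3-channel input is converted by ITU-R 601 luminance weighting
#' (0.299 R + 0.587 G + 0.114 B); single-channel input passes through as a
#' float matrix. Images are stored rows = y, columns = x, 0-based pixel
#' coordinates with centers at integers.
#'
#' @param x an H x W matrix, or an H x W x C array with C = 1 or 3.
#' @return H x W numeric matrix.
#' @examples
#' toGrayscale(matrix(5, 4, 4))[1, 1]
#' @export
toGrayscale <- function(x) {
  if (is.matrix(x)) {
    storage.mode(x) <- "double"
    return(x)
  }
  d <- dim(x)
  if (length(d) == 3 && d[3] == 1)
    return(toGrayscale(x[, , 1]))
  if (length(d) == 3 && d[3] == 3)
    return(0.299 * x[, , 1] + 0.587 * x[, , 2] + 0.114 * x[, , 3])
  stop("unsupported raster: expected a matrix or an H x W x {1,3} array")
}

#' Read a raster file as a grayscale intensity matrix
#'
#' Reads PNG/TIFF/JPEG via EBImage and returns an H x W matrix scaled to
#' `[0, 255]` (rows = y, columns = x).
#'
#' @param path image file.
#' @return H x W numeric matrix of intensities in `[0, 255]`.
#' @export
readImageGray <- function(path) {
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  d <- dim(a)
  m <- if (length(d) == 2) t(a)
       else if (length(d) == 3) toGrayscale(aperm(a[, , seq_len(min(d[3], 3)),
                                                    drop = FALSE],
                                                  c(2, 1, 3)))
       else stop("unsupported image layout in ", path)
  255 * m
}

#' Gaussian-smoothed gradient-magnitude field
#'
#' Smooths the image with a Gaussian of scale `sigma` (kernel truncated at
#' 3 sigma, replicate boundary), takes the central-difference gradient
#' magnitude `sqrt(gx^2 + gy^2)`, and min-max normalizes to `[0, 255]`
#' (a constant image maps to the all-zero field). Deterministic.
#'
#' @param image H x W numeric matrix of intensities.
#' @param sigma Gaussian smoothing scale in px, > 0.
#' @return A [GradientField-class].
#' @examples
#' img <- matrix(0, 20, 20); img[, 11:20] <- 255
#' f <- gaussianGradient(img, sigma = 2)
#' range(gradientValues(f))
#' @export
gaussianGradient <- function(image, sigma = 2) {
  image <- toGrayscale(image)
  if (any(!is.finite(image))) stop("image contains non-finite pixels")
  if (length(sigma) != 1 || sigma <= 0) stop("sigma must be > 0")
  s <- .gaussSmooth(image, sigma)
  gr <- .centralGradient(s)
  mag <- sqrt(gr$gx^2 + gr$gy^2)
  lo <- min(mag); hi <- max(mag)
  g <- if (hi > lo) (mag - lo) / (hi - lo) * 255 else matrix(0, nrow(mag), ncol(mag))
  new("GradientField", g = g, sigma = sigma)
}

#' Sample a gradient field with bilinear interpolation
#'
#' Points outside the image domain are clamped to the nearest valid pixel
#' border before interpolation, so edge-touching annotations sample the
#' border value instead of erroring.
#'
#' @param field a [GradientField-class].
#' @param p a length-2 vector `(x, y)` or an n x 2 matrix of points in
#'   pixel coordinates (0-based, pixel centers at integers).
#' @return numeric vector of interpolated gradient values.
#' @export
sampleBilinear <- function(field, p) {
  g <- field@g
  H <- nrow(g); W <- ncol(g)
  if (is.null(dim(p))) p <- matrix(p, ncol = 2)
  x <- pmin(pmax(p[, 1], 0), W - 1)
  y <- pmin(pmax(p[, 2], 0), H - 1)
  x0 <- floor(x); y0 <- floor(y)
  x1 <- pmin(x0 + 1, W - 1); y1 <- pmin(y0 + 1, H - 1)
  fx <- x - x0; fy <- y - y0
  i00 <- cbind(y0 + 1, x0 + 1); i01 <- cbind(y0 + 1, x1 + 1)
  i10 <- cbind(y1 + 1, x0 + 1); i11 <- cbind(y1 + 1, x1 + 1)
  (1 - fy) * ((1 - fx) * g[i00] + fx * g[i01]) +
    fy * ((1 - fx) * g[i10] + fx * g[i11])
}
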