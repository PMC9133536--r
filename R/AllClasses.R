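#' @import methods
NULL

#' Closed polygon contour of label points
#'
#' An ordered sequence of sub-pixel label points outlining one object
#' (typically a cytoplasm or nucleus). The polygon is closed implicitly:
#' indexing is circular and the first point is never duplicated at the end.
#' Coordinates follow the package-wide convention: `(x, y)` with x = column,
#' y = row, 0-based, pixel centers at integer coordinates.
#'
#' @slot points numeric matrix, n x 2, columns x and y in pixels.
#' @slot label free-text class tag, e.g. `"cytoplasm"` or `"nucleus"`.
#' @slot shapeType annotation shape type; the pipeline corrects `"polygon"`
#'   shapes only, anything else is carried through untouched.
#' @slot meta list of extra annotation fields preserved across I/O.
#' @export
setClass("Contour",
  representation(points = "matrix", label = "character",
                 shapeType = "character", meta = "list"),
  prototype(points = matrix(numeric(0), 0, 2), label = "",
            shapeType = "polygon", meta = list()))

setValidity("Contour", function(object) {
  p <- object@points
  if (!is.numeric(p) || ncol(p) != 2)
    return("points must be a numeric matrix with 2 columns (x, y)")
  if (any(!is.finite(p)))
    return("contour points must be finite")
  need <- if (identical(object@shapeType, "polygon")) 3L else 1L
  if (nrow(p) < need)
    return(sprintf("a %s needs at least %d points", object@shapeType, need))
  TRUE
})

#' Construct a Contour
#'
#' @param points n x 2 numeric matrix (or coercible) of (x, y) pixel
#'   coordinates, 0-based, pixel centers at integers.
#' @param label class tag.
#' @param shapeType annotation shape type, default `"polygon"`.
#' @param meta list of extra fields to carry through I/O.
#' @return A [Contour-class] object.
#' @examples
#' sq <- Contour(rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)), "cytoplasm")
#' nPoints(sq)
#' @export
Contour <- function(points, label = "", shapeType = "polygon", meta = list()) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  dimnames(points) <- NULL
  new("Contour", points = points, label = as.character(label),
      shapeType = as.character(shapeType), meta = meta)
}

#' @describeIn Contour coordinates as an n x 2 matrix.
#' @param x,object a `Contour`.
#' @export
setGeneric("contourPoints", function(x) standardGeneric("contourPoints"))

#' @rdname Contour
#' @export
setMethod("contourPoints", "Contour", function(x) x@points)

#' @describeIn Contour the label tag.
#' @export
setGeneric("contourLabel", function(x) standardGeneric("contourLabel"))

#' @rdname Contour
#' @export
setMethod("contourLabel", "Contour", function(x) x@label)

#' @describeIn Contour number of stored points.
#' @export
setGeneric("nPoints", function(x) standardGeneric("nPoints"))

#' @rdname Contour
#' @export
setMethod("nPoints", "Contour", function(x) nrow(x@points))

setMethod("show", "Contour", function(object) {
  cat(sprintf("Contour(%s): %d points, shape '%s'\n",
              if (nzchar(object@label)) object@label else "<unlabeled>",
              nrow(object@points), object@shapeType))
  if (nrow(object@points)) {
    b <- apply(object@points, 2, range)
    cat(sprintf("  bbox: x [%.2f, %.2f], y [%.2f, %.2f]\n",
                b[1, 1], b[2, 1], b[1, 2], b[2, 2]))
  }
})

#' Gaussian-smoothed gradient-magnitude field
#'
#' The guidance image for point correction: gradient magnitude of the
#' Gaussian-smoothed intensity image, min-max normalized to `[0, 255]`
#' (identically zero for a constant image). Same height/width as the source.
#'
#' @slot g numeric matrix (rows = y, columns = x) of normalized gradient
#'   magnitude in `[0, 255]`.
#' @slot sigma Gaussian smoothing scale in pixels.
#' @export
setClass("GradientField", representation(g = "matrix", sigma = "numeric"))

setValidity("GradientField", function(object) {
  if (!is.numeric(object@g) || any(!is.finite(object@g)))
    return("gradient field must be finite numeric")
  if (length(object@sigma) != 1L || object@sigma <= 0)
    return("sigma must be a single positive number")
  if (min(object@g) < 0 || max(object@g) > 255 + 1e-9)
    return("gradient values must lie in [0, 255]")
  TRUE
})

setMethod("show", "GradientField", function(object) {
  cat(sprintf("GradientField: %d x %d px, sigma = %g, range [%.1f, %.1f]\n",
              nrow(object@g), ncol(object@g), object@sigma,
              min(object@g), max(object@g)))
})

#' @describeIn GradientField the H x W matrix of normalized gradient values.
#' @param x,object a `GradientField`.
#' @export
setGeneric("gradientValues", function(x) standardGeneric("gradientValues"))

#' @rdname GradientField
#' @export
setMethod("gradientValues", "GradientField", function(x) x@g)

#' Full parameter set of the label-correction pipeline
#'
#' Bundles the parameters of the three correction stages with their standard
#' defaults: gradient-guided point correction (search radius `r = 15` px,
#' gradient-variation threshold `lambdaT = 4` in normalized gradient units,
#' kernel bandwidth `h1 = r/2`), point interpolation (`gap = 1` px), and
#' local point smoothing (group size `ng = 14` points, regression bandwidth
#' `h2 = rf/2` with group radius `rf = floor((ng - 1)/2)`, group-center
#' stride fixed at 1). `gradientSigma` is the Gaussian scale of the guidance
#' field. The `do*` switches disable individual stages for ablation; all
#' three off makes the pipeline the identity.
#'
#' @slot r search radius along the contour normal, px.
#' @slot lambdaT gradient-variation threshold.
#' @slot h1 candidate-weight kernel bandwidth, px.
#' @slot gap maximum allowed spacing between adjacent points, px.
#' @slot ng smoothing group size, points.
#' @slot h2 regression kernel bandwidth, px.
#' @slot gradientSigma Gaussian smoothing scale of the gradient field, px.
#' @slot doGPC,doPI,doLPS stage switches.
#' @export
setClass("LLPCConfig",
  representation(r = "numeric", lambdaT = "numeric", h1 = "numeric",
                 gap = "numeric", ng = "numeric", h2 = "numeric",
                 gradientSigma = "numeric", doGPC = "logical",
                 doPI = "logical", doLPS = "logical"))

setValidity("LLPCConfig", function(object) {
  if (object@r < 1 || object@r != round(object@r))
    return("r must be an integer >= 1")
  if (object@lambdaT < 0) return("lambdaT must be >= 0")
  if (object@h1 <= 0) return("h1 must be > 0")
  if (object@gap <= 0) return("gap must be > 0")
  if (object@ng < 3) return("ng must be >= 3")
  if (object@h2 <= 0) return("h2 must be > 0")
  if (object@gradientSigma <= 0) return("gradientSigma must be > 0")
  TRUE
})

#' Construct an LLPCConfig
#'
#' `h1` defaults to `r/2` and `h2` to `rf/2` (with `rf = floor((ng - 1)/2)`),
#' recomputed when `r` or `ng` is overridden; pass them explicitly to pin
#' other values.
#'
#' @param r search radius, px.
#' @param lambdaT gradient-variation threshold.
#' @param h1 kernel bandwidth for candidate weights; default `r/2`.
#' @param gap maximum adjacent spacing after interpolation, px.
#' @param ng smoothing group size.
#' @param h2 regression bandwidth; default `floor((ng - 1)/2)/2`.
#' @param gradientSigma Gaussian scale of the gradient field, px.
#' @param doGPC,doPI,doLPS enable/disable the three stages.
#' @return An [LLPCConfig-class].
#' @examples
#' cfg <- llpcConfig()          # standard defaults
#' llpcConfig(r = 7)            # h1 follows r/2 = 3.5
#' @export
llpcConfig <- function(r = 15, lambdaT = 4, h1 = NULL, gap = 1, ng = 14,
                       h2 = NULL, gradientSigma = 2,
                       doGPC = TRUE, doPI = TRUE, doLPS = TRUE) {
  if (is.null(h1)) h1 <- r / 2
  if (is.null(h2)) h2 <- floor((ng - 1) / 2) / 2
  new("LLPCConfig", r = as.numeric(r), lambdaT = as.numeric(lambdaT),
      h1 = as.numeric(h1), gap = as.numeric(gap), ng = as.numeric(ng),
      h2 = as.numeric(h2), gradientSigma = as.numeric(gradientSigma),
      doGPC = isTRUE(doGPC), doPI = isTRUE(doPI), doLPS = isTRUE(doLPS))
}

#' @describeIn llpcConfig group radius `rf = floor((ng - 1)/2)` of a config.
#' @param config an `LLPCConfig`.
#' @export
groupRadius <- function(config) floor((config@ng - 1) / 2)

setMethod("show", "LLPCConfig", function(object) {
  cat(sprintf(paste0(
    "LLPCConfig: r = %g, lambdaT = %g, h1 = %g | gap = %g | ng = %g, ",
    "h2 = %g | sigma = %g\n  stages: GPC %s, PI %s, LPS %s\n"),
    object@r, object@lambdaT, object@h1, object@gap, object@ng, object@h2,
    object@gradientSigma,
    if (object@doGPC) "on" else "off",
    if (object@doPI) "on" else "off",
    if (object@doLPS) "on" else "off"))
})

#' One image's set of labeled polygons (labelme dialect)
#'
#' @slot imagePath path recorded in the annotation file.
#' @slot imageHeight,imageWidth image size, px.
#' @slot shapes list of [Contour-class] objects.
#' @slot meta unknown top-level fields preserved for round-trip.
#' @export
setClass("AnnotationDocument",
  representation(imagePath = "character", imageHeight = "numeric",
                 imageWidth = "numeric", shapes = "list", meta = "list"),
  prototype(imagePath = "", imageHeight = 0, imageWidth = 0,
            shapes = list(), meta = list()))

setValidity("AnnotationDocument", function(object) {
  if (object@imageHeight < 1 || object@imageWidth < 1)
    return("image dimensions must be >= 1 px")
  if (!all(vapply(object@shapes, is, logical(1), class2 = "Contour")))
    return("shapes must all be Contour objects")
  TRUE
})

#' Construct an AnnotationDocument
#'
#' @param shapes list of [Contour-class] objects.
#' @param imageHeight,imageWidth image size in px.
#' @param imagePath recorded image path.
#' @param meta extra top-level fields to preserve.
#' @return An [AnnotationDocument-class].
#' @export
annotationDocument <- function(shapes, imageHeight, imageWidth,
                               imagePath = "", meta = list()) {
  new("AnnotationDocument", imagePath = as.character(imagePath),
      imageHeight = as.numeric(imageHeight),
      imageWidth = as.numeric(imageWidth),
      shapes = shapes, meta = meta)
}

#' @describeIn annotationDocument list of contours in document order.
#' @param x a document.
#' @export
setGeneric("shapes", function(x) standardGeneric("shapes"))

#' @rdname annotationDocument
#' @export
setMethod("shapes", "AnnotationDocument", function(x) x@shapes)

setMethod("show", "AnnotationDocument", function(object) {
  cat(sprintf("AnnotationDocument: %d x %d px, %d shape(s)\n",
              object@imageWidth, object@imageHeight, length(object@shapes)))
  labs <- vapply(object@shapes, contourLabel, character(1))
  if (length(labs)) {
    tab <- table(labs)
    cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
        "\n", sep = "")
  }
})
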