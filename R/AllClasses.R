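#' @import methods
NULL

#' GrayImage: an 8-bit grayscale raster
#'
#' A 2D integer-valued raster with values in [0, 255] and an optional
#' isotropic physical pixel spacing in millimetres.  This is the carrier
#' for radiograph regions throughout the fractal pipeline.
#'
#' @slot pixels integer-valued numeric matrix, values 0--255, rows are
#'   image rows (top-left origin, row-major).
#' @slot spacing physical size of one pixel in mm, or \code{NA_real_} when
#'   unknown.
#'
#' @seealso [grayImage()], [loadGrayImage()], [extractROI()]
#' @exportClass GrayImage
setClass("GrayImage",
  representation(pixels = "matrix", spacing = "numeric"),
  prototype(pixels = matrix(0, 1, 1), spacing = NA_real_)
)

setValidity("GrayImage", function(object) {
  p <- object@pixels
  if (!is.numeric(p)) return("pixels must be a numeric matrix")
  if (nrow(p) < 1L || ncol(p) < 1L) return("image must have height >= 1 and width >= 1")
  if (anyNA(p)) return("pixels must not contain NA")
  if (any(p < 0) || any(p > 255)) return("pixel values must lie in [0, 255]")
  if (any(p != round(p))) return("pixel values must be integers (8-bit)")
  s <- object@spacing
  if (length(s) != 1L) return("spacing must be a single value")
  if (!is.na(s) && s <= 0) return("spacing, when present, must be > 0")
  TRUE
})

#' BinaryImage: a binary mask
#'
#' Logical raster; \code{TRUE} marks the foreground phase.  After
#' binarization of a processed radiograph the foreground is the dark
#' (trabecular bone) phase; morphology, skeletonization and box counting
#' all operate on it.
#'
#' @slot mask logical matrix, \code{TRUE} = foreground.
#' @seealso [binarize()], [erodeDilate()], [skeletonize()], [boxCount()]
#' @exportClass BinaryImage
setClass("BinaryImage",
  representation(mask = "matrix"),
  prototype(mask = matrix(FALSE, 1, 1))
)

setValidity("BinaryImage", function(object) {
  m <- object@mask
  if (!is.logical(m)) return("mask must be a logical matrix")
  if (nrow(m) < 1L || ncol(m) < 1L) return("mask must have height >= 1 and width >= 1")
  if (anyNA(m)) return("mask must not contain NA")
  TRUE
})

#' ROISpec: a square region of interest
#'
#' Names a square tile of a radiograph.  Coordinates are 0-based with the
#' origin at the image's top-left corner; the rectangle is half-open,
#' covering rows \code{originRow .. originRow + size - 1}.  The side
#' length defaults to the standardized 100 pixels.
#'
#' @slot label free-text label, conventionally ROI1..ROI4.
#' @slot originRow,originCol top-left corner, 0-based pixels.
#' @slot size side length in pixels (>= 9 so the smallest box grid is
#'   meaningful; default 100).
#' @seealso [roiSpec()], [extractROI()]
#' @exportClass ROISpec
setClass("ROISpec",
  representation(label = "character", originRow = "integer",
                 originCol = "integer", size = "integer"),
  prototype(label = "ROI", originRow = 0L, originCol = 0L, size = 100L)
)

setValidity("ROISpec", function(object) {
  if (length(object@label) != 1L) return("label must be a single string")
  if (object@originRow < 0L || object@originCol < 0L)
    return("ROI origin coordinates must be >= 0")
  if (object@size < 9L) return("ROI size must be >= 9 pixels")
  TRUE
})

#' FDConfig: parameters of the fractal-dimension pipeline
#'
#' Tunables of the blur-subtract-binarize-open-skeletonize-count chain.
#' Defaults reproduce the standard protocol: Gaussian sigma 35 px, gray
#' offset 128, threshold 128, one 3x3 erosion + dilation, and box widths
#' 2, 3, 4, 6, 8, 12, 16, 32 and 64 pixels.
#'
#' @slot blurSigma Gaussian standard deviation, pixels (> 0).
#' @slot offset gray value added after subtraction, 0--255.
#' @slot threshold binarization gray level, 0--255; pixels strictly below
#'   it become foreground (bone).
#' @slot morphRadius structuring-element radius, pixels; radius 1 is the
#'   3x3 square.
#' @slot morphIterations erosion passes (and then the same number of
#'   dilation passes).
#' @slot boxSizes strictly increasing box widths, pixels.
#' @seealso [fdConfig()], [computeFD()]
#' @exportClass FDConfig
setClass("FDConfig",
  representation(blurSigma = "numeric", offset = "numeric",
                 threshold = "numeric", morphRadius = "integer",
                 morphIterations = "integer", boxSizes = "numeric"),
  prototype(blurSigma = 35, offset = 128, threshold = 128,
            morphRadius = 1L, morphIterations = 1L,
            boxSizes = c(2, 3, 4, 6, 8, 12, 16, 32, 64))
)

setValidity("FDConfig", function(object) {
  if (object@blurSigma <= 0) return("blurSigma must be > 0")
  if (object@offset < 0 || object@offset > 255) return("offset must lie in [0, 255]")
  if (object@threshold < 0 || object@threshold > 255) return("threshold must lie in [0, 255]")
  if (object@morphRadius < 1L) return("morphRadius must be >= 1")
  if (object@morphIterations < 1L) return("morphIterations must be >= 1")
  b <- object@boxSizes
  if (length(b) < 2L) return("at least two box sizes are required")
  if (any(b < 1) || any(b != round(b))) return("box sizes must be integers >= 1")
  if (any(diff(b) <= 0)) return("box sizes must be strictly increasing")
  TRUE
})

#' BoxCountResult: occupied-box counts and the log-log fit
#'
#' For each box width s the raster is tiled by an axis-aligned grid of
#' s x s boxes anchored at the top-left corner (partial boxes at the
#' right/bottom edges included) and boxes containing at least one
#' foreground pixel are counted.  An ordinary least-squares fit of
#' ln(count) on ln(s) yields the fractal dimension as minus the slope.
#'
#' @slot sizes box widths used, pixels.
#' @slot counts occupied boxes per width.
#' @slot logSizes,logCounts natural-log transforms.
#' @slot slope,intercept,rSquared OLS fit of logCounts on logSizes.
#' @slot fd the fractal dimension, \code{-slope}.
#' @seealso [boxCount()]
#' @exportClass BoxCountResult
setClass("BoxCountResult",
  representation(sizes = "numeric", counts = "numeric",
                 logSizes = "numeric", logCounts = "numeric",
                 slope = "numeric", intercept = "numeric",
                 rSquared = "numeric", fd = "numeric")
)

setValidity("BoxCountResult", function(object) {
  if (length(object@sizes) != length(object@counts))
    return("sizes and counts must have equal length")
  if (length(object@sizes) < 2L) return("at least two sizes are required")
  if (any(object@counts < 1)) return("counts must be positive")
  if (!isTRUE(all.equal(object@fd, -object@slope)))
    return("fd must equal -slope")
  TRUE
})

#' FDResult: the fractal dimension of one region of interest
#'
#' @slot roiLabel the label of the analysed region.
#' @slot fd the box-counting fractal dimension (dimensionless).
#' @slot boxcount the underlying [BoxCountResult-class].
#' @slot intermediates optionally retained stage rasters (named list:
#'   roi, blurred, corrected, binary, opened, skeleton), empty otherwise.
#' @seealso [computeFD()]
#' @exportClass FDResult
setClass("FDResult",
  representation(roiLabel = "character", fd = "numeric",
                 boxcount = "BoxCountResult", intermediates = "list"),
)

#' CorticalLandmarks: annotated geometry for the MCW measurement
#'
#' The mental foramen centre plus two polylines tracing the inferior
#' (outer) border and the endosteal (inner) margin of the mandibular
#' cortex, in image pixel coordinates (row, col), with the physical pixel
#' spacing.
#'
#' @slot foramenCenter numeric (row, col), pixels.
#' @slot inferiorBorder n x 2 matrix of (row, col) vertices, >= 2 points.
#' @slot endostealMargin n x 2 matrix of (row, col) vertices, >= 2 points.
#' @slot side "left" or "right".
#' @slot spacing mm per pixel (> 0).
#' @seealso [corticalLandmarks()], [measureMCW()]
#' @exportClass CorticalLandmarks
setClass("CorticalLandmarks",
  representation(foramenCenter = "numeric", inferiorBorder = "matrix",
                 endostealMargin = "matrix", side = "character",
                 spacing = "numeric")
)

setValidity("CorticalLandmarks", function(object) {
  if (length(object@foramenCenter) != 2L) return("foramenCenter must be (row, col)")
  for (nm in c("inferiorBorder", "endostealMargin")) {
    m <- slot(object, nm)
    if (!is.numeric(m) || ncol(m) != 2L) return(sprintf("%s must be an n x 2 matrix", nm))
    if (nrow(m) < 2L) return(sprintf("%s must have at least 2 points", nm))
  }
  if (!object@side %in% c("left", "right")) return("side must be 'left' or 'right'")
  if (length(object@spacing) != 1L || is.na(object@spacing) || object@spacing <= 0)
    return("spacing must be a single value > 0")
  # image rows grow downwards: the foramen sits above the inferior border
  if (object@foramenCenter[1] >= max(object@inferiorBorder[, 1]))
    return("foramenCenter must lie above the inferior border in image coordinates")
  TRUE
})

#' MCWResult: a mandibular cortical width measurement
#'
#' @slot widthMM cortical width in millimetres.
#' @slot probeLine 2 x 2 matrix; rows are the intersection points (row,
#'   col) of the perpendicular probe with the endosteal margin and the
#'   inferior border.
#' @slot side "left" or "right".
#' @seealso [measureMCW()]
#' @exportClass MCWResult
setClass("MCWResult",
  representation(widthMM = "numeric", probeLine = "matrix", side = "character")
)

setValidity("MCWResult", function(object) {
  if (length(object@widthMM) != 1L || object@widthMM <= 0)
    return("widthMM must be a single value > 0")
  if (!all(dim(object@probeLine) == c(2L, 2L)))
    return("probeLine must be a 2 x 2 matrix of intersection points")
  TRUE
})
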