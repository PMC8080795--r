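#' Pixel raster of an image
#'
#' @param x a [GrayImage-class]
#' @return numeric matrix of 8-bit values.
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' Foreground mask of a binary image
#'
#' @param x a [BinaryImage-class]
#' @return logical matrix, \code{TRUE} = foreground.
#' @export
setGeneric("mask", function(x) standardGeneric("mask"))

#' Physical pixel spacing in millimetres
#'
#' @param x a [GrayImage-class] or [CorticalLandmarks-class]
#' @return mm per pixel, or \code{NA} if unknown.
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' Fractal dimension stored in a result object
#'
#' @param x an [FDResult-class] or [BoxCountResult-class]
#' @return the fractal dimension (dimensionless).
#' @export
setGeneric("fdValue", function(x) standardGeneric("fdValue"))

#' Cortical width in millimetres
#'
#' @param x an [MCWResult-class]
#' @return width in mm.
#' @export
setGeneric("widthMM", function(x) standardGeneric("widthMM"))

#' @rdname pixels
setMethod("pixels", "GrayImage", function(x) x@pixels)

#' @rdname mask
setMethod("mask", "BinaryImage", function(x) x@mask)

#' @rdname spacing
setMethod("spacing", "GrayImage", function(x) x@spacing)

#' @rdname spacing
setMethod("spacing", "CorticalLandmarks", function(x) x@spacing)

#' @rdname fdValue
setMethod("fdValue", "FDResult", function(x) x@fd)

#' @rdname fdValue
setMethod("fdValue", "BoxCountResult", function(x) x@fd)

#' @rdname widthMM
setMethod("widthMM", "MCWResult", function(x) x@widthMM)

#' @describeIn pixels image dimensions (rows, cols)
#' @export
setMethod("dim", "GrayImage", function(x) dim(x@pixels))

#' @describeIn mask mask dimensions (rows, cols)
#' @export
setMethod("dim", "BinaryImage", function(x) dim(x@mask))

setMethod("show", "GrayImage", function(object) {
  cat(sprintf("GrayImage %d x %d, range [%d, %d], spacing %s mm/px\n",
              nrow(object@pixels), ncol(object@pixels),
              min(object@pixels), max(object@pixels),
              ifelse(is.na(object@spacing), "NA", format(object@spacing))))
})

setMethod("show", "BinaryImage", function(object) {
  cat(sprintf("BinaryImage %d x %d, %d foreground pixels (%.1f%%)\n",
              nrow(object@mask), ncol(object@mask), sum(object@mask),
              100 * mean(object@mask)))
})

setMethod("show", "ROISpec", function(object) {
  cat(sprintf("ROISpec '%s': origin (%d, %d), size %d px\n",
              object@label, object@originRow, object@originCol, object@size))
})

setMethod("show", "FDConfig", function(object) {
  cat("FDConfig\n")
  cat(sprintf("  blurSigma: %g px   offset: %g   threshold: %g\n",
              object@blurSigma, object@offset, object@threshold))
  cat(sprintf("  morphology: radius %d, %d iteration(s)\n",
              object@morphRadius, object@morphIterations))
  cat("  boxSizes:", paste(object@boxSizes, collapse = ", "), "\n")
})

setMethod("show", "BoxCountResult", function(object) {
  cat(sprintf("BoxCountResult: FD = %.4f (r^2 = %.4f) over %d box sizes\n",
              object@fd, object@rSquared, length(object@sizes)))
})

setMethod("show", "FDResult", function(object) {
  cat(sprintf("FDResult '%s': FD = %.4f (fit r^2 = %.4f)\n",
              object@roiLabel, object@fd, object@boxcount@rSquared))
})

setMethod("show", "CorticalLandmarks", function(object) {
  cat(sprintf("CorticalLandmarks (%s): foramen (%.1f, %.1f), %d + %d border points, %.4g mm/px\n",
              object@side, object@foramenCenter[1], object@foramenCenter[2],
              nrow(object@inferiorBorder), nrow(object@endostealMargin),
              object@spacing))
})

setMethod("show", "MCWResult", function(object) {
  cat(sprintf("MCWResult (%s): width %.4f mm\n", object@side, object@widthMM))
})
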