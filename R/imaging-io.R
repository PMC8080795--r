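#' Construct a GrayImage
#'
#' @param pixels numeric matrix of integer values in [0, 255].
#' @param spacing optional physical pixel size, mm (isotropic).
#' @return a [GrayImage-class]
#' @examples
#' img <- grayImage(matrix(128, 10, 10), spacing = 0.1)
#' dim(img)
#' @export
grayImage <- function(pixels, spacing = NA_real_) {
  storage.mode(pixels) <- "double"
  new("GrayImage", pixels = pixels, spacing = as.numeric(spacing))
}

#' Construct a BinaryImage
#'
#' @param mask logical matrix; \code{TRUE} = foreground.
#' @return a [BinaryImage-class]
#' @export
binaryImage <- function(mask) {
  storage.mode(mask) <- "logical"
  new("BinaryImage", mask = mask)
}

#' Construct an ROISpec
#'
#' Coordinates are 0-based from the image's top-left corner; the region
#' is the half-open square \code{[origin, origin + size)}.
#'
#' @param label region label (e.g. "ROI1").
#' @param originRow,originCol top-left corner, 0-based pixels.
#' @param size side length in pixels; default 100 (the standardized tile).
#' @return an [ROISpec-class]
#' @export
roiSpec <- function(label, originRow, originCol, size = 100L) {
  new("ROISpec", label = as.character(label),
      originRow = as.integer(originRow), originCol = as.integer(originCol),
      size = as.integer(size))
}

## luminance weights for colour -> gray conversion (ITU-R BT.601)
.LUMA <- c(0.299, 0.587, 0.114)

#' Read an 8-bit grayscale image from PNG or TIFF
#'
#' Colour inputs are collapsed to a single channel with the standard
#' luminance weights (0.299 R + 0.587 G + 0.114 B; an alpha channel is
#' ignored) and rounded to integers.  Higher bit depths are linearly
#' rescaled to 0--255 (round(v * 255 / vmax)).
#'
#' @param path file path; format is taken from the extension
#'   (.png / .tif / .tiff).  Multi-page TIFFs yield the first page.
#' @param spacingMM optional physical pixel size in mm to attach.
#' @return a [GrayImage-class]
#' @seealso [saveGrayImage()], [extractROI()]
#' @export
loadGrayImage <- function(path, spacingMM = NA_real_) {
  if (!file.exists(path))
    stop("cannot read image: file does not exist: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = {
      x <- tiff::readTIFF(path, all = FALSE)
      if (is.list(x)) x[[1]] else x
    },
    stop("unsupported image format '", ext, "' for ", path,
         " (PNG and TIFF are accepted)")
  )
  ## readPNG / readTIFF normalize to [0, 1] regardless of source bit
  ## depth, so round(v * 255) is the linear rescale to 8 bits.
  if (length(dim(arr)) == 3L) {
    nc <- dim(arr)[3]
    gray <- if (nc >= 3L) {
      .LUMA[1] * arr[, , 1] + .LUMA[2] * arr[, , 2] + .LUMA[3] * arr[, , 3]
    } else {
      arr[, , 1]  # gray (+ alpha): take the gray channel
    }
  } else {
    gray <- arr
  }
  px <- round(gray * 255)
  if (nrow(px) < 1L || ncol(px) < 1L)
    stop("zero-area image: ", path)
  grayImage(px, spacing = spacingMM)
}

#' Write a GrayImage to PNG or TIFF
#'
#' The written file round-trips bit-exactly through [loadGrayImage()].
#'
#' @param image a [GrayImage-class]
#' @param path output path; .png, .tif or .tiff.
#' @return \code{path}, invisibly.
#' @export
saveGrayImage <- function(image, path) {
  stopifnot(is(image, "GrayImage"))
  ext <- tolower(tools::file_ext(path))
  norm <- image@pixels / 255
  switch(ext,
    png  = png::writePNG(norm, path),
    tif  = ,
    tiff = tiff::writeTIFF(norm, path, bits.per.sample = 8L),
    stop("unsupported image format '", ext, "' for ", path)
  )
  invisible(path)
}

#' Extract a square region of interest
#'
#' Returns a copy of the \code{size} x \code{size} tile at the ROI's
#' 0-based origin.  The tile must lie entirely inside the image: regions
#' that stick out raise an error rather than being clipped, since the
#' downstream texture analysis depends on a fixed tile size.
#'
#' @param image a [GrayImage-class]
#' @param roi an [ROISpec-class]
#' @return a \code{size} x \code{size} [GrayImage-class]; spacing is
#'   propagated from the source.
#' @examples
#' img <- grayImage(matrix(sample(0:255, 200 * 200, TRUE), 200, 200))
#' tile <- extractROI(img, roiSpec("ROI1", 50, 50))
#' dim(tile)
#' @export
extractROI <- function(image, roi) {
  stopifnot(is(image, "GrayImage"), is(roi, "ROISpec"))
  h <- nrow(image@pixels); w <- ncol(image@pixels)
  r0 <- roi@originRow; c0 <- roi@originCol; s <- roi@size
  if (r0 + s > h || c0 + s > w)
    stop(sprintf(
      "ROI '%s' exceeds image bounds: rows [%d, %d) x cols [%d, %d) vs image %d x %d (overlap %d x %d)",
      roi@label, r0, r0 + s, c0, c0 + s, h, w,
      max(0L, min(r0 + s, h) - r0), max(0L, min(c0 + s, w) - c0)))
  grayImage(image@pixels[(r0 + 1L):(r0 + s), (c0 + 1L):(c0 + s), drop = FALSE],
            spacing = image@spacing)
}
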