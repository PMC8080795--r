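#' Construct an FDConfig
#'
#' @param blurSigma Gaussian standard deviation in pixels (default 35).
#' @param offset gray value added after background subtraction (default 128).
#' @param threshold binarization gray level (default 128); pixels strictly
#'   below it become foreground.
#' @param morphRadius structuring-element radius; 1 = 3x3 square.
#' @param morphIterations erosion (then dilation) passes.
#' @param boxSizes strictly increasing box widths in pixels.
#' @return an [FDConfig-class]
#' @export
fdConfig <- function(blurSigma = 35, offset = 128, threshold = 128,
                     morphRadius = 1L, morphIterations = 1L,
                     boxSizes = c(2, 3, 4, 6, 8, 12, 16, 32, 64)) {
  new("FDConfig", blurSigma = blurSigma, offset = offset,
      threshold = threshold, morphRadius = as.integer(morphRadius),
      morphIterations = as.integer(morphIterations),
      boxSizes = as.numeric(boxSizes))
}

## ---- Gaussian blur --------------------------------------------------------

## normalized 1D Gaussian, truncated at 4 sigma
.gaussKernel <- function(sigma) {
  r <- ceiling(4 * sigma)
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

## map out-of-range 1-based indices back inside by symmetric reflection
## (edge pixel repeated: 0 -> 1, -1 -> 2, n+1 -> n, ...)
.reflectIndex <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  repeat {
    below <- i < 1L
    if (any(below)) i[below] <- 1L - i[below]
    above <- i > n
    if (any(above)) i[above] <- 2L * n + 1L - i[above]
    if (!any(i < 1L | i > n)) return(i)
  }
}

## n x n matrix applying the truncated Gaussian along one axis, with
## out-of-image samples taken by mirror reflection or edge replication
.blurOperator <- function(n, sigma, border = "reflect") {
  k <- .gaussKernel(sigma)
  r <- (length(k) - 1L) / 2L
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    src <- if (border == "reflect") .reflectIndex(i + (-r:r), n)
           else pmin(pmax(i + (-r:r), 1L), n)
    w <- vapply(split(k, src), sum, numeric(1))
    A[i, as.integer(names(w))] <- w
  }
  A
}

## operators are expensive for large sigma; memoize on (n, sigma, border)
.blurCache <- new.env(parent = emptyenv())

.cachedBlurOperator <- function(n, sigma, border) {
  key <- paste(n, sigma, border, sep = "_")
  if (is.null(.blurCache[[key]]))
    .blurCache[[key]] <- .blurOperator(n, sigma, border)
  .blurCache[[key]]
}

#' Gaussian blur of a grayscale image
#'
#' Separable Gaussian convolution with symmetric reflection at the
#' borders (the package's documented convention) and the kernel
#' truncated at 4 sigma; the result is re-quantized to integers 0--255,
#' mirroring 8-bit processing.  With a large sigma (default pipeline:
#' 35 px on a 100 px tile) this estimates the large-scale brightness
#' field of the region.  \code{border = "replicate"} (constant edge
#' extension) is available for comparison; it tracks linear trends
#' across the tile about twice as closely as mirroring when the kernel
#' support exceeds the tile.
#'
#' @param image a [GrayImage-class]
#' @param sigma standard deviation in pixels (> 0).
#' @param border out-of-image handling, "reflect" (default) or
#'   "replicate".
#' @return blurred [GrayImage-class]
#' @seealso [subtractOffset()]
#' @export
gaussianBlur <- function(image, sigma, border = c("reflect", "replicate")) {
  stopifnot(is(image, "GrayImage"))
  border <- match.arg(border)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("sigma must be a single value > 0")
  p <- image@pixels
  Ar <- .cachedBlurOperator(nrow(p), sigma, border)
  Ac <- if (ncol(p) == nrow(p)) Ar else .cachedBlurOperator(ncol(p), sigma, border)
  out <- Ar %*% p %*% t(Ac)
  grayImage(pmin(pmax(round(out), 0), 255), spacing = image@spacing)
}

#' Subtract a background estimate and add a gray offset
#'
#' Per pixel: \code{clamp(original - blurred + offset, 0, 255)}.  With
#' the default offset 128 the corrected image is centred on mid-gray, so
#' texture darker than its local background falls below 128.
#'
#' @param original,blurred [GrayImage-class] objects of identical shape.
#' @param offset gray value added at each pixel (default 128).
#' @return corrected [GrayImage-class]
#' @export
subtractOffset <- function(original, blurred, offset = 128) {
  stopifnot(is(original, "GrayImage"), is(blurred, "GrayImage"))
  if (!identical(dim(original@pixels), dim(blurred@pixels)))
    stop("original and blurred images must have the same shape")
  out <- original@pixels - blurred@pixels + offset
  grayImage(pmin(pmax(round(out), 0), 255), spacing = original@spacing)
}

#' Threshold a grayscale image into a binary mask
#'
#' Foreground (the trabecular-bone phase, rendered black by the
#' preprocessing chain) is every pixel with value strictly below the
#' threshold; pixels at or above it are background (marrow spaces).
#'
#' @param image a [GrayImage-class]
#' @param threshold gray level, default 128.
#' @return a [BinaryImage-class]
#' @export
binarize <- function(image, threshold = 128) {
  stopifnot(is(image, "GrayImage"))
  binaryImage(image@pixels < threshold)
}

## shift a logical matrix by (dr, dc), filling exposed cells with `fill`
.shiftMask <- function(m, dr, dc, fill) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  sr <- max(1L, 1L - dr):min(h, h - dr)
  sc <- max(1L, 1L - dc):min(w, w - dc)
  if (length(sr) > 0L && length(sc) > 0L)
    out[sr + dr, sc + dc] <- m[sr, sc]
  out
}

## separable min (erode) / max (dilate) filter with a (2r+1)^2 square
## structuring element; outside the raster is background
.erode1 <- function(m, r) {
  for (d in seq_len(r)) m <- m & .shiftMask(m, -1L, 0L, FALSE) & .shiftMask(m, 1L, 0L, FALSE)
  for (d in seq_len(r)) m <- m & .shiftMask(m, 0L, -1L, FALSE) & .shiftMask(m, 0L, 1L, FALSE)
  m
}

.dilate1 <- function(m, r) {
  for (d in seq_len(r)) m <- m | .shiftMask(m, -1L, 0L, FALSE) | .shiftMask(m, 1L, 0L, FALSE)
  for (d in seq_len(r)) m <- m | .shiftMask(m, 0L, -1L, FALSE) | .shiftMask(m, 0L, 1L, FALSE)
  m
}

#' Morphological opening of a binary mask
#'
#' \code{iterations} erosions followed by the same number of dilations
#' with a (2 radius + 1)^2 square structuring element; pixels outside the
#' raster count as background.  Opening removes speckle smaller than the
#' structuring element while leaving large convex regions intact.
#'
#' @param maskImg a [BinaryImage-class]
#' @param radius structuring-element radius (>= 1); 1 = 3x3 square.
#' @param iterations erosion/dilation passes (>= 1).
#' @return opened [BinaryImage-class]
#' @export
erodeDilate <- function(maskImg, radius = 1L, iterations = 1L) {
  stopifnot(is(maskImg, "BinaryImage"))
  if (radius < 1L) stop("radius must be >= 1")
  if (iterations < 1L) stop("iterations must be >= 1")
  m <- maskImg@mask
  for (i in seq_len(iterations)) m <- .erode1(m, radius)
  for (i in seq_len(iterations)) m <- .dilate1(m, radius)
  binaryImage(m)
}

## ---- skeletonization ------------------------------------------------------

## 8-neighbourhood of the padded mask, as a list P2..P9 clockwise from
## north, each an h x w 0/1 matrix aligned with the unpadded image
.neighbours <- function(P) {
  h <- nrow(P) - 2L; w <- ncol(P) - 2L
  core <- function(dr, dc) P[(2L + dr):(h + 1L + dr), (2L + dc):(w + 1L + dc), drop = FALSE]
  list(p2 = core(-1L, 0L), p3 = core(-1L, 1L), p4 = core(0L, 1L),
       p5 = core(1L, 1L),  p6 = core(1L, 0L),  p7 = core(1L, -1L),
       p8 = core(0L, -1L), p9 = core(-1L, -1L))
}

## thinning conditions for one pixel of the padded 0/1 matrix P at
## (padded) position (r, c); sub = 1 or 2 selects the subiteration
.thinOK <- function(P, r, c, sub) {
  p2 <- P[r - 1L, c]; p3 <- P[r - 1L, c + 1L]; p4 <- P[r, c + 1L]
  p5 <- P[r + 1L, c + 1L]; p6 <- P[r + 1L, c]; p7 <- P[r + 1L, c - 1L]
  p8 <- P[r, c - 1L]; p9 <- P[r - 1L, c - 1L]
  b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
  if (b < 2L || b > 6L) return(FALSE)
  seqv <- c(p2, p3, p4, p5, p6, p7, p8, p9, p2)
  a <- sum(seqv[-9L] == 0L & seqv[-1L] == 1L)
  if (a != 1L) return(FALSE)
  if (sub == 1L) (p2 * p4 * p6 == 0L) && (p4 * p6 * p8 == 0L)
  else           (p2 * p4 * p8 == 0L) && (p2 * p6 * p8 == 0L)
}

#' Skeletonize a binary mask
#'
#' Topology-preserving two-subiteration thinning (Zhang--Suen
#' conditions) of the foreground down to 1-pixel-wide 8-connected
#' curves.  Within each subiteration, candidate pixels found in parallel
#' are deleted sequentially, re-checking the connectivity condition
#' against the current raster before each deletion; this keeps the
#' number of 8-connected components exactly unchanged (naive parallel
#' deletion can annihilate 2x2 blocks).  Isolated pixels and curve
#' endpoints are never removed.
#'
#' @param maskImg a [BinaryImage-class]
#' @return skeleton [BinaryImage-class]; a subset of the input foreground.
#' @export
skeletonize <- function(maskImg) {
  stopifnot(is(maskImg, "BinaryImage"))
  h <- nrow(maskImg@mask); w <- ncol(maskImg@mask)
  P <- matrix(0L, h + 2L, w + 2L)
  P[2:(h + 1L), 2:(w + 1L)] <- maskImg@mask * 1L
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      nb <- .neighbours(P)
      core <- P[2:(h + 1L), 2:(w + 1L), drop = FALSE]
      b <- nb$p2 + nb$p3 + nb$p4 + nb$p5 + nb$p6 + nb$p7 + nb$p8 + nb$p9
      cyc <- list(nb$p2, nb$p3, nb$p4, nb$p5, nb$p6, nb$p7, nb$p8, nb$p9, nb$p2)
      a <- Reduce(`+`, lapply(1:8, function(i) (cyc[[i]] == 0L) * (cyc[[i + 1L]] == 1L)))
      cond <- core == 1L & b >= 2L & b <= 6L & a == 1L
      cond <- cond & if (sub == 1L) {
        (nb$p2 * nb$p4 * nb$p6 == 0L) & (nb$p4 * nb$p6 * nb$p8 == 0L)
      } else {
        (nb$p2 * nb$p4 * nb$p8 == 0L) & (nb$p2 * nb$p6 * nb$p8 == 0L)
      }
      cand <- which(cond, arr.ind = TRUE)
      if (nrow(cand) == 0L) next
      ## sequential re-check: each deletion must still satisfy the
      ## conditions on the current (partially thinned) raster
      for (i in seq_len(nrow(cand))) {
        r <- cand[i, 1L] + 1L; c <- cand[i, 2L] + 1L
        if (.thinOK(P, r, c, sub)) {
          P[r, c] <- 0L
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  binaryImage(P[2:(h + 1L), 2:(w + 1L), drop = FALSE] == 1L)
}

## ---- box counting ---------------------------------------------------------

#' Box-counting analysis of a binary mask
#'
#' For each box width s the raster is tiled with an axis-aligned grid of
#' s x s boxes anchored at the top-left corner; partial boxes at the
#' right and bottom edges are included.  Boxes containing at least one
#' foreground pixel are counted, and ln(count) is regressed on ln(s) by
#' ordinary least squares.  The fractal dimension is minus the slope.
#'
#' @param maskImg a [BinaryImage-class] with at least one foreground pixel.
#' @param sizes at least two distinct box widths, pixels; each must be
#'   between 1 and the larger raster dimension.
#' @return a [BoxCountResult-class]
#' @examples
#' sq <- binaryImage(matrix(TRUE, 64, 64))
#' fdValue(boxCount(sq, c(2, 4, 8, 16, 32, 64)))  # exactly 2
#' @export
boxCount <- function(maskImg, sizes = c(2, 3, 4, 6, 8, 12, 16, 32, 64)) {
  stopifnot(is(maskImg, "BinaryImage"))
  sizes <- sort(unique(as.numeric(sizes)))
  if (length(sizes) < 2L) stop("at least two distinct box sizes are required")
  if (any(sizes < 1) || any(sizes != round(sizes)))
    stop("box sizes must be integers >= 1")
  m <- maskImg@mask
  if (any(sizes > max(dim(m))))
    stop("box sizes must not exceed the raster extent")
  fg <- which(m, arr.ind = TRUE)
  if (nrow(fg) == 0L)
    stop("degenerate input: empty mask has no defined fractal dimension")
  counts <- vapply(sizes, function(s) {
    tiles <- (fg[, 1L] - 1L) %/% s * (ncol(m) %/% s + 2L) + (fg[, 2L] - 1L) %/% s
    length(unique(tiles))
  }, numeric(1))
  ls <- log(sizes); lc <- log(counts)
  sxx <- sum((ls - mean(ls))^2)
  slope <- sum((ls - mean(ls)) * (lc - mean(lc))) / sxx
  intercept <- mean(lc) - slope * mean(ls)
  sstot <- sum((lc - mean(lc))^2)
  r2 <- if (sstot > 0) 1 - sum((lc - (intercept + slope * ls))^2) / sstot else NA_real_
  new("BoxCountResult", sizes = sizes, counts = counts,
      logSizes = ls, logCounts = lc, slope = slope, intercept = intercept,
      rSquared = r2, fd = -slope)
}

#' Fractal dimension of a region of interest
#'
#' Runs the full texture-analysis chain on one ROI: crop, Gaussian blur,
#' background subtraction with gray offset, binarization (dark phase =
#' bone), morphological opening, skeletonization, and box counting.  The
#' chain is fully deterministic.
#'
#' @param image the source [GrayImage-class] radiograph.
#' @param roi an [ROISpec-class] lying inside the image.
#' @param config an [FDConfig-class]; defaults reproduce the standard
#'   protocol.
#' @param keepIntermediates retain the stage rasters in the result
#'   (\code{roi}, \code{blurred}, \code{corrected}, \code{binary},
#'   \code{opened}, \code{skeleton}).
#' @return an [FDResult-class]
#' @examples
#' spec <- syntheticSpec("fbm_texture", side = 120, hurst = 0.5, seed = 7)
#' img <- makeTrabecularTexture(spec)
#' res <- computeFD(img, roiSpec("ROI1", 10, 10, 100))
#' fdValue(res)
#' @export
computeFD <- function(image, roi, config = fdConfig(), keepIntermediates = FALSE) {
  stopifnot(is(image, "GrayImage"), is(roi, "ROISpec"), is(config, "FDConfig"))
  if (any(config@boxSizes > roi@size))
    stop("box sizes must not exceed the ROI side (", roi@size, " px)")
  tile <- extractROI(image, roi)
  blurred <- gaussianBlur(tile, config@blurSigma)
  corrected <- subtractOffset(tile, blurred, config@offset)
  binary <- binarize(corrected, config@threshold)
  opened <- erodeDilate(binary, config@morphRadius, config@morphIterations)
  skel <- skeletonize(opened)
  if (!any(skel@mask))
    stop("degenerate input: ROI '", roi@label,
         "' has no trabecular signal after preprocessing (empty skeleton)")
  bc <- boxCount(skel, config@boxSizes)
  new("FDResult", roiLabel = roi@label, fd = bc@fd, boxcount = bc,
      intermediates = if (keepIntermediates)
        list(roi = tile, blurred = blurred, corrected = corrected,
             binary = binary, opened = opened, skeleton = skel)
      else list())
}

#' Export a box-count analysis as a data frame
#'
#' One row per box size with the occupied-box count and the natural-log
#' coordinates of the fitted line; suitable for writing to CSV.
#'
#' @param x a [BoxCountResult-class]
#' @return data.frame with columns size, count, log_size, log_count.
#' @export
boxCountTable <- function(x) {
  stopifnot(is(x, "BoxCountResult"))
  data.frame(size = x@sizes, count = x@counts,
             log_size = x@logSizes, log_count = x@logCounts)
}
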