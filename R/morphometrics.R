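#' Construct CorticalLandmarks
#'
#' @param foramenCenter numeric (row, col) of the mental foramen centre,
#'   pixels.
#' @param inferiorBorder n x 2 matrix (row, col) tracing the lower edge
#'   of the mandibular cortex, >= 2 points.
#' @param endostealMargin n x 2 matrix (row, col) tracing the inner
#'   (upper) edge of the cortex, >= 2 points.
#' @param side "left" or "right".
#' @param spacing mm per pixel (> 0).
#' @return a [CorticalLandmarks-class]
#' @export
corticalLandmarks <- function(foramenCenter, inferiorBorder, endostealMargin,
                              side = "right", spacing) {
  new("CorticalLandmarks",
      foramenCenter = as.numeric(foramenCenter),
      inferiorBorder = .asPointMatrix(inferiorBorder),
      endostealMargin = .asPointMatrix(endostealMargin),
      side = side, spacing = as.numeric(spacing))
}

.asPointMatrix <- function(x) {
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  colnames(m) <- NULL
  m
}

## intersections of the line p0 + t*dir with a polyline; returns the
## parameters t of all crossings (linear interpolation along segments)
.lineCrossings <- function(p0, dir, poly) {
  ts <- numeric(0)
  for (i in seq_len(nrow(poly) - 1L)) {
    a <- poly[i, ]; b <- poly[i + 1L, ]
    ## p0 + t*dir = a + u*(b - a),  u in [0, 1]
    M <- cbind(dir, a - b)
    if (abs(det(M)) < 1e-12) next  # segment parallel to the probe
    sol <- unname(solve(M, a - p0))
    if (sol[2] >= -1e-9 && sol[2] <= 1 + 1e-9) ts <- c(ts, sol[1])
  }
  ts
}

#' Measure the mandibular cortical width
#'
#' Reproduces the standard construction: the local direction of the
#' inferior cortical border is fitted below the mental foramen, a probe
#' line is drawn through the foramen centre perpendicular to that
#' direction, and the width is the distance between the probe's
#' crossings of the endosteal margin and the inferior border, converted
#' to millimetres.
#'
#' The tangent is the principal axis (total least squares) of the
#' inferior-border points whose column lies within \code{window} pixels
#' of the foramen column, which makes the construction invariant under
#' rigid rotation of the scene.  If the probe crosses a polyline more
#' than once the crossing nearest the foramen is used.
#'
#' @param landmarks a [CorticalLandmarks-class]
#' @param window half-width, in pixels along the border, of the
#'   tangent-fitting neighbourhood under the foramen (default 50).
#' @return an [MCWResult-class]
#' @examples
#' lm <- corticalLandmarks(
#'   foramenCenter = c(100, 250),
#'   inferiorBorder = cbind(180, seq(150, 350, by = 10)),
#'   endostealMargin = cbind(140, seq(150, 350, by = 10)),
#'   side = "right", spacing = 0.1)
#' widthMM(measureMCW(lm))  # 4.0 mm
#' @export
measureMCW <- function(landmarks, window = 50) {
  stopifnot(is(landmarks, "CorticalLandmarks"))
  fc <- landmarks@foramenCenter
  inf <- landmarks@inferiorBorder
  endo <- landmarks@endostealMargin

  ## local tangent of the inferior border under the foramen
  near <- abs(inf[, 2] - fc[2]) <= window
  pts <- inf[near, , drop = FALSE]
  if (nrow(pts) < 2L) pts <- inf  # fall back to the whole trace
  pts <- unique(pts)
  if (nrow(pts) < 2L)
    stop("degenerate tangent window: fewer than 2 distinct inferior-border points")
  ctr <- sweep(pts, 2, colMeans(pts))
  sv <- svd(ctr, nu = 0, nv = 2)
  tangent <- sv$v[, 1]
  normal <- c(-tangent[2], tangent[1])  # perpendicular probe direction

  tEndo <- .lineCrossings(fc, normal, endo)
  if (length(tEndo) == 0L)
    stop("geometry error: the perpendicular probe does not cross the endosteal margin")
  tInf <- .lineCrossings(fc, normal, inf)
  if (length(tInf) == 0L)
    stop("geometry error: the perpendicular probe does not cross the inferior border")
  tEndo <- tEndo[which.min(abs(tEndo))]
  tInf <- tInf[which.min(abs(tInf))]

  pEndo <- fc + tEndo * normal
  pInf <- fc + tInf * normal
  width <- abs(tInf - tEndo) * landmarks@spacing  # |normal| = 1
  if (width <= 0)
    stop("geometry error: coincident border crossings give zero cortical width")
  new("MCWResult", widthMM = width,
      probeLine = rbind(pEndo, pInf), side = landmarks@side)
}

.MCI_LEVELS <- c("C1", "C2", "C3")

#' Tabulate mandibular cortical index grades
#'
#' MCI grading (Klemetti's C1/C2/C3 appearance classes of the endosteal
#' cortical margin) is a human visual assessment; this function
#' validates recorded grades and cross-tabulates them by group,
#' preserving zero cells, so the table can feed a chi-square test of
#' independence.
#'
#' @param grade character vector of grades; each must be "C1", "C2" or
#'   "C3".
#' @param group parallel vector of group labels.
#' @return an integer matrix, groups x grades (columns C1, C2, C3);
#'   zero-row matrix for empty input.
#' @examples
#' tabulateMCI(c(rep("C1", 12), rep("C2", 3)), rep("FAP", 15))
#' @export
tabulateMCI <- function(grade, group) {
  if (length(grade) != length(group))
    stop("grade and group must have the same length")
  if (length(grade) == 0L) {
    out <- matrix(0L, 0L, length(.MCI_LEVELS),
                  dimnames = list(NULL, .MCI_LEVELS))
    return(out)
  }
  bad <- !grade %in% .MCI_LEVELS
  if (any(bad))
    stop("invalid MCI grade(s): ",
         paste(sprintf("record %d = '%s'", which(bad), grade[bad]), collapse = ", "),
         " (grades must be C1, C2 or C3)")
  tab <- table(factor(group), factor(grade, levels = .MCI_LEVELS))
  out <- matrix(as.integer(tab), nrow(tab), ncol(tab),
                dimnames = dimnames(tab))
  out
}
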