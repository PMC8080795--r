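#' Specification of a synthetic fixture
#'
#' All test and harness inputs are generated from a single spec object;
#' given the same spec (seed included) every generator is a pure
#' function and returns bit-identical output.
#'
#' @param kind one of "sierpinski_carpet", "sierpinski_triangle",
#'   "line", "filled_square", "random_dots", "fbm_texture",
#'   "cortex_scene", "group_samples".
#' @param depth recursion depth for the fractal kinds (>= 0).
#' @param side raster side length in pixels; for carpet fixtures
#'   3^depth must divide side, for triangle fixtures 2^depth.
#' @param hurst roughness parameter of the fBm texture, in (0, 1);
#'   lower values give rougher (more complex) texture.
#' @param gradientAmplitude gray levels of the linear brightness ramp
#'   superimposed corner-to-corner on the texture (default 0).
#' @param dotDensity foreground fraction for "random_dots", in (0, 1).
#' @param groupParams for "group_samples": named list of
#'   \code{list(n, mean, sd)} per group.
#' @param seed RNG seed; mandatory for the stochastic kinds and
#'   recorded in the output's \code{spec} attribute.
#' @return list of class \code{SyntheticSpec}.
#' @export
syntheticSpec <- function(kind, depth = 0L, side = 100L, hurst = 0.5,
                          gradientAmplitude = 0, dotDensity = 0.1,
                          groupParams = NULL, seed = NULL) {
  kinds <- c("sierpinski_carpet", "sierpinski_triangle", "line",
             "filled_square", "random_dots", "fbm_texture",
             "cortex_scene", "group_samples")
  if (!kind %in% kinds)
    stop("unknown synthetic kind '", kind, "'")
  if (depth < 0) stop("depth must be >= 0")
  if (side < 1) stop("side must be >= 1")
  if (kind == "sierpinski_carpet" && side %% 3^depth != 0)
    stop("side must be a multiple of 3^depth for carpet fixtures")
  if (kind == "sierpinski_triangle" && side %% 2^depth != 0)
    stop("side must be a multiple of 2^depth for triangle fixtures")
  if (kind == "fbm_texture" && (hurst <= 0 || hurst >= 1))
    stop("hurst must lie strictly in (0, 1)")
  if (kind == "random_dots" && (dotDensity <= 0 || dotDensity >= 1))
    stop("dotDensity must lie strictly in (0, 1)")
  if (kind %in% c("random_dots", "fbm_texture", "group_samples") && is.null(seed))
    stop("a seed is required for stochastic kind '", kind, "'")
  if (kind == "group_samples") {
    if (is.null(groupParams) || length(groupParams) < 1L)
      stop("groupParams are required for group_samples")
    for (g in groupParams) {
      if (g$n < 2) stop("each group needs n >= 2")
      if (g$sd < 0) stop("group sd must be >= 0")
    }
  }
  structure(list(kind = kind, depth = as.integer(depth),
                 side = as.integer(side), hurst = hurst,
                 gradientAmplitude = gradientAmplitude,
                 dotDensity = dotDensity, groupParams = groupParams,
                 seed = seed),
            class = "SyntheticSpec")
}

## run expr with a fixed seed, restoring the caller's RNG state after
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Generate an exact binary fixture of known dimension
#'
#' Deterministic constructions whose box-counting behaviour is known in
#' closed form: the depth-k Sierpinski carpet on side 3^k has exactly
#' 8^k foreground pixels and log-log slope -ln 8 / ln 3; a line has
#' dimension 1 and a filled square dimension 2.  "random_dots" draws an
#' iid Bernoulli mask from the spec's seed.
#'
#' @param spec a [syntheticSpec()] with a fractal/line/square/dots kind.
#' @return a [BinaryImage-class]; the spec is attached as attribute
#'   \code{"spec"}.
#' @examples
#' sum(mask(makeFractalMask(syntheticSpec("sierpinski_carpet", depth = 2, side = 9))))
#' @export
makeFractalMask <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  n <- spec$side
  m <- switch(spec$kind,
    filled_square = matrix(TRUE, n, n),
    line = {
      out <- matrix(FALSE, n, n)
      out[ceiling(n / 2), ] <- TRUE
      out
    },
    sierpinski_carpet = {
      u <- n %/% 3L^spec$depth
      idx0 <- (seq_len(n) - 1L) %/% u  # base-3^depth cell index per pixel
      keep <- matrix(TRUE, n, n)
      for (lev in seq_len(spec$depth)) {
        digR <- (idx0 %/% 3L^(spec$depth - lev)) %% 3L
        hole <- outer(digR == 1L, digR == 1L, `&`)
        keep <- keep & !hole
      }
      keep
    },
    sierpinski_triangle = {
      u <- n %/% 2L^spec$depth
      idx0 <- (seq_len(n) - 1L) %/% u
      outer(idx0, idx0, function(i, j) bitwAnd(i, j) == 0L)
    },
    random_dots = .withSeed(spec$seed,
      matrix(stats::runif(n * n) < spec$dotDensity, n, n)),
    stop("kind '", spec$kind, "' is not a binary fixture kind")
  )
  out <- binaryImage(m)
  attr(out, "spec") <- spec
  out
}

#' Generate a trabecular-like grayscale texture
#'
#' Spectral synthesis of a fractional-Brownian surface: a complex
#' Gaussian spectrum is shaped so the power spectral density falls off
#' as f^-(2 hurst + 2), inverse-transformed, rescaled to 0--255, and
#' optionally overlaid with a linear brightness ramp of
#' \code{gradientAmplitude} gray levels running corner-to-corner (the
#' stand-in for the large-scale brightness variation of a panoramic
#' radiograph).  Lower Hurst values give rougher texture and a higher
#' pipeline fractal dimension.
#'
#' @param spec a [syntheticSpec()] with kind "fbm_texture" (needs
#'   \code{side}, \code{hurst}, \code{gradientAmplitude}, \code{seed}).
#' @return a [GrayImage-class] with the spec attached as attribute
#'   \code{"spec"}.
#' @export
makeTrabecularTexture <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  if (spec$kind != "fbm_texture") stop("spec kind must be 'fbm_texture'")
  n <- spec$side
  field <- .withSeed(spec$seed, {
    k <- seq_len(n) - 1L
    k <- ifelse(k <= n %/% 2L, k, k - n) / n  # DFT frequencies
    rad <- sqrt(outer(k^2, k^2, `+`))
    amp <- rad^(-(spec$hurst + 1))
    amp[1L, 1L] <- 0  # zero-mean surface
    z <- matrix(stats::rnorm(n * n), n, n) + 1i * matrix(stats::rnorm(n * n), n, n)
    Re(stats::fft(z * amp, inverse = TRUE)) / n
  })
  ## fixed texture contrast (mean 100, sd 28 gray levels) independent of
  ## the ramp, so images with different gradient settings share an
  ## identical base texture and differ only by the additive brightness
  ## field; the chosen level leaves headroom for ramps up to ~60 levels
  ## with only rare tail clipping
  if (abs(spec$gradientAmplitude) >= 150)
    stop("gradientAmplitude must stay below 150 gray levels")
  scaled <- 100 + 28 * (field - mean(field)) / stats::sd(field)
  if (spec$gradientAmplitude != 0) {
    ii <- row(scaled) - 1L; jj <- col(scaled) - 1L
    scaled <- scaled + spec$gradientAmplitude * (ii + jj) / (2 * (n - 1))
  }
  out <- grayImage(pmin(pmax(round(scaled), 0), 255))
  attr(out, "spec") <- spec
  out
}

#' Render a cortical-band scene with consistent landmarks
#'
#' Draws the lower mandibular cortex as two parallel dark band edges a
#' known physical width apart, rigidly rotated by \code{rotationDeg}
#' about the raster centre, together with [CorticalLandmarks-class]
#' annotations (foramen centre above the bands, both border polylines).
#' [measureMCW()] on the returned landmarks recovers
#' \code{trueWidthMM}, so the scene is a closed-loop harness for the
#' width measurement.
#'
#' @param spec a [syntheticSpec()] with kind "cortex_scene" (uses
#'   \code{side}).
#' @param trueWidthMM cortical width to render, mm (> 0).
#' @param rotationDeg rigid rotation of the scene, degrees.
#' @param spacingMM pixel size, mm (default 0.1).
#' @param side "left" or "right" label for the landmarks.
#' @return list with elements \code{image} ([GrayImage-class]) and
#'   \code{landmarks} ([CorticalLandmarks-class]).
#' @export
makeCortexScene <- function(spec, trueWidthMM, rotationDeg = 0,
                            spacingMM = 0.1, side = "right") {
  stopifnot(inherits(spec, "SyntheticSpec"))
  if (spec$kind != "cortex_scene") stop("spec kind must be 'cortex_scene'")
  if (trueWidthMM <= 0) stop("trueWidthMM must be > 0")
  n <- spec$side
  wpx <- trueWidthMM / spacingMM
  if (wpx > n / 3)
    stop("cortical width ", trueWidthMM, " mm (", wpx,
         " px) exceeds the raster: at most side/3 = ", n / 3, " px fits")
  ctr <- c((n + 1) / 2, (n + 1) / 2)
  th <- rotationDeg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)  # (row, col) rotation
  rot <- function(p) sweep(sweep(p, 2, ctr) %*% t(R), 2, ctr, `+`)

  ## unrotated geometry: endosteal margin above, inferior border below
  halfLen <- 0.35 * n
  xs <- seq(-halfLen, halfLen, by = 1)
  rowEndo <- ctr[1] + 0.1 * n
  rowInf <- rowEndo + wpx
  endo <- cbind(rowEndo, ctr[2] + xs)
  inf <- cbind(rowInf, ctr[2] + xs)
  foramen <- c(rowEndo - 0.15 * n, ctr[2])

  lmk <- corticalLandmarks(
    foramenCenter = drop(rot(matrix(foramen, 1))),
    inferiorBorder = rot(inf),
    endostealMargin = rot(endo),
    side = side, spacing = spacingMM)

  ## raster: dark cortex band between the two borders on a bright field
  ii <- matrix(rep(seq_len(n), n), n)
  jj <- t(ii)
  ## rotate each pixel back to the unrotated frame and test band membership
  rel <- cbind(as.vector(ii) - ctr[1], as.vector(jj) - ctr[2]) %*% R  # inverse rotation
  yUn <- rel[, 1] + ctr[1]
  px <- ifelse(yUn >= rowEndo & yUn <= rowInf, 70, 190)
  img <- grayImage(matrix(px, n, n), spacing = spacingMM)
  list(image = img, landmarks = lmk)
}

#' Draw two-group samples with prescribed moments
#'
#' Each group is drawn from a normal distribution with its (mean, sd);
#' with \code{exact = TRUE} the draw is affinely post-standardized so the
#' sample mean and SD match the targets exactly, making summary-based
#' statistics on the generated data deterministic.
#'
#' @param spec a [syntheticSpec()] with kind "group_samples"
#'   (\code{groupParams} = named list of \code{list(n, mean, sd)};
#'   \code{seed} mandatory).
#' @param exact match the sample moments exactly (default FALSE).
#' @return data.frame with columns \code{group} (factor) and
#'   \code{value}; the spec is attached as attribute \code{"spec"}.
#' @export
makeGroupSamples <- function(spec, exact = FALSE) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  if (spec$kind != "group_samples") stop("spec kind must be 'group_samples'")
  nm <- names(spec$groupParams)
  if (is.null(nm)) nm <- paste0("group", seq_along(spec$groupParams))
  out <- .withSeed(spec$seed, {
    parts <- lapply(seq_along(spec$groupParams), function(i) {
      g <- spec$groupParams[[i]]
      v <- if (g$sd == 0) rep(g$mean, g$n) else {
        z <- stats::rnorm(g$n, g$mean, g$sd)
        if (exact) g$mean + g$sd * as.vector(scale(z)) else z
      }
      data.frame(group = nm[i], value = v)
    })
    do.call(rbind, parts)
  })
  out$group <- factor(out$group, levels = nm)
  attr(out, "spec") <- spec
  out
}
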