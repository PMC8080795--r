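test_that("exact fractal fixtures have their closed-form pixel counts", {
  carpet <- makeFractalMask(syntheticSpec("sierpinski_carpet", depth = 2, side = 9))
  expect_identical(sum(mask(carpet)), 64L)         # 8^2
  carpet4 <- makeFractalMask(syntheticSpec("sierpinski_carpet", depth = 4, side = 81))
  expect_identical(sum(mask(carpet4)), 4096L)      # 8^4

  tri <- makeFractalMask(syntheticSpec("sierpinski_triangle", depth = 4, side = 16))
  expect_identical(sum(mask(tri)), 81L)            # 3^4

  line <- makeFractalMask(syntheticSpec("line", side = 100))
  expect_identical(sum(mask(line)), 100L)
  expect_identical(sum(rowSums(mask(line)) > 0), 1L)

  expect_error(syntheticSpec("sierpinski_carpet", depth = 3, side = 50),
               "multiple of 3")
  expect_error(syntheticSpec("random_dots", side = 10, dotDensity = 0.1),
               "seed")
})

test_that("random dot masks are seeded, reproducible, binomially calibrated", {
  spec <- syntheticSpec("random_dots", side = 100, dotDensity = 0.1, seed = 17)
  m1 <- makeFractalMask(spec)
  m2 <- makeFractalMask(spec)
  expect_identical(mask(m1), mask(m2))
  # 99% binomial bounds around n p = 1000
  cnt <- sum(mask(m1))
  bound <- qnorm(0.995) * sqrt(10000 * 0.1 * 0.9)
  expect_lt(abs(cnt - 1000), bound)
  # a different seed gives a different mask
  m3 <- makeFractalMask(syntheticSpec("random_dots", side = 100,
                                      dotDensity = 0.1, seed = 18))
  expect_false(identical(mask(m1), mask(m3)))
})

test_that("fBm textures are pure functions of their spec and leave the RNG alone", {
  spec <- syntheticSpec("fbm_texture", side = 64, hurst = 0.4,
                        gradientAmplitude = 30, seed = 5)
  a <- makeTrabecularTexture(spec)
  set.seed(123); before <- rnorm(3)
  b <- makeTrabecularTexture(spec)
  expect_identical(pixels(a), pixels(b))
  # generator restores the caller's RNG stream
  set.seed(123)
  mid <- makeTrabecularTexture(spec)
  expect_identical(rnorm(3), before)
  expect_error(syntheticSpec("fbm_texture", hurst = 1.2, seed = 1), "hurst")
})

test_that("rougher fBm (lower Hurst) yields higher pipeline FD", {
  roi <- roiSpec("R", 0, 0, 100)
  fdAt <- function(h, s) {
    img <- makeTrabecularTexture(syntheticSpec("fbm_texture", side = 100,
                                               hurst = h, seed = s))
    fdValue(computeFD(img, roi))
  }
  fds <- vapply(1:8, function(s) c(fdAt(0.3, s), fdAt(0.8, s)), numeric(2))
  expect_gt(median(fds[1, ]), median(fds[2, ]))
})

test_that("cortex scenes invert through measureMCW and validate their width", {
  spec <- syntheticSpec("cortex_scene", side = 512)
  sc <- makeCortexScene(spec, trueWidthMM = 4.0, rotationDeg = 0)
  expect_s4_class(sc$image, "GrayImage")
  expect_equal(widthMM(measureMCW(sc$landmarks)), 4.0, tolerance = 1e-6)

  rot <- makeCortexScene(spec, trueWidthMM = 3.4, rotationDeg = 25)
  expect_equal(widthMM(measureMCW(rot$landmarks)), 3.4, tolerance = 1e-3)

  # the rendered raster really contains a dark band of the stated width
  px <- pixels(sc$image)
  midCol <- px[, 256]
  expect_equal(sum(midCol == 70) * 0.1, 4.0, tolerance = 0.2)

  expect_error(makeCortexScene(syntheticSpec("cortex_scene", side = 100),
                               trueWidthMM = 50, spacingMM = 0.1),
               "exceeds the raster")
})

test_that("group samples match printed summaries exactly when asked", {
  spec <- syntheticSpec("group_samples",
                        groupParams = list(FAP = list(n = 15, mean = 1.162, sd = 0.076),
                                           control = list(n = 45, mean = 1.253, sd = 0.067)),
                        seed = 7)
  d <- makeGroupSamples(spec, exact = TRUE)
  expect_identical(nrow(d), 60L)
  byg <- split(d$value, d$group)
  expect_equal(mean(byg$FAP), 1.162, tolerance = 1e-12)
  expect_equal(sd(byg$FAP), 0.076, tolerance = 1e-12)
  expect_equal(mean(byg$control), 1.253, tolerance = 1e-12)
  expect_equal(sd(byg$control), 0.067, tolerance = 1e-12)
  # the pooled t on the realized data is then the printed-summary t
  tt <- tTestPooled(byg$FAP, byg$control)
  expect_equal(tt$t,
               tTestFromSummary(c(15, 1.162, 0.076), c(45, 1.253, 0.067))$t,
               tolerance = 1e-9)

  # degenerate group: sd = 0 duplicates the mean
  d0 <- makeGroupSamples(syntheticSpec("group_samples",
                                       groupParams = list(g = list(n = 2, mean = 3, sd = 0)),
                                       seed = 1))
  expect_identical(d0$value, c(3, 3))

  # reproducibility without exact matching
  dA <- makeGroupSamples(spec)
  dB <- makeGroupSamples(spec)
  expect_identical(dA$value, dB$value)
})
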