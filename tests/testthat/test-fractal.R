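test_that("Gaussian blur preserves constants, symmetry, and matches dense convolution", {
  const <- grayImage(matrix(128, 40, 40))
  expect_true(all(pixels(gaussianBlur(const, 5)) == 128))

  # single bright pixel: symmetric response, maximum at the source
  spot <- matrix(0, 31, 31); spot[16, 16] <- 255
  b <- pixels(gaussianBlur(grayImage(spot), 2))
  expect_identical(which.max(b), which(row(b) == 16 & col(b) == 16))
  expect_identical(b, b[31:1, ])          # vertical mirror
  expect_identical(b, t(b))               # diagonal symmetry

  # step edge along one axis: every row must equal the 1D dense-convolution oracle
  step <- matrix(rep(c(rep(40, 25), rep(220, 25)), each = 12), 12, 50)
  got <- pixels(gaussianBlur(grayImage(step), 2))
  want <- round(oracleConvolve1D(step[1, ], 2))
  for (i in seq_len(nrow(got))) expect_equal(unname(got[i, ]), want)

  expect_error(gaussianBlur(const, 0), "sigma")
  expect_error(gaussianBlur(const, -3), "sigma")
})

test_that("background subtraction offsets and clamps to 8 bits", {
  a <- grayImage(matrix(200, 10, 10))
  expect_true(all(pixels(subtractOffset(a, a, 128)) == 128))
  hi <- subtractOffset(grayImage(matrix(255, 4, 4)), grayImage(matrix(0, 4, 4)), 128)
  expect_true(all(pixels(hi) == 255))
  lo <- subtractOffset(grayImage(matrix(0, 4, 4)), grayImage(matrix(200, 4, 4)), 128)
  expect_true(all(pixels(lo) == 0))
  expect_error(subtractOffset(a, grayImage(matrix(0, 4, 4))), "shape")
})

test_that("binarization marks the dark phase as foreground", {
  expect_false(any(mask(binarize(grayImage(matrix(128, 8, 8)), 128))))
  two <- grayImage(matrix(c(0, 255), 8, 8))
  expect_identical(mask(binarize(two, 128)), pixels(two) == 0)
  chk <- matrix(100, 8, 8); chk[(row(chk) + col(chk)) %% 2 == 0] <- 200
  expect_identical(mask(binarize(grayImage(chk), 128)), chk == 100)
})

test_that("opening removes speckle, keeps convex blocks, and matches the set-theoretic oracle", {
  speck <- matrix(FALSE, 9, 9); speck[5, 5] <- TRUE
  expect_false(any(mask(erodeDilate(binaryImage(speck), 1, 1))))

  block <- matrix(FALSE, 20, 20); block[6:15, 6:15] <- TRUE
  expect_identical(mask(erodeDilate(binaryImage(block), 1, 1)), block)

  for (seed in 1:4) {
    m <- mask(makeFractalMask(syntheticSpec("random_dots", side = 64,
                                            dotDensity = 0.35, seed = seed)))
    expect_identical(mask(erodeDilate(binaryImage(m), 1, 1)), oracleOpening(m, 1))
  }
  # two iterations = erode twice then dilate twice
  m <- mask(makeFractalMask(syntheticSpec("random_dots", side = 48,
                                          dotDensity = 0.6, seed = 9)))
  got <- mask(erodeDilate(binaryImage(m), 1, 2))
  want <- oracleFilter(oracleFilter(oracleFilter(oracleFilter(m, 1, all), 1, all), 1, any), 1, any)
  expect_identical(got, want)

  expect_error(erodeDilate(binaryImage(block), 0), "radius")
  expect_error(erodeDilate(binaryImage(block), 1, 0), "iterations")
})

test_that("skeletonization thins to 1-px curves and preserves 8-connected components", {
  # 5-px-wide bar -> a 1-px line spanning (almost) the same columns
  bar <- matrix(FALSE, 20, 40); bar[8:12, 5:36] <- TRUE
  sk <- mask(skeletonize(binaryImage(bar)))
  expect_true(all(colSums(sk) <= 1))            # 1 px wide
  expect_true(all(colSums(sk[, 10:31]) == 1))   # continuous through the middle
  expect_gte(sum(sk), (36 - 5 + 1) - 2 * 2)     # extent minus end effects
  expect_true(all(bar[sk]))                      # skeleton subset of input

  empty <- binaryImage(matrix(FALSE, 10, 10))
  expect_identical(mask(skeletonize(empty)), mask(empty))

  # worst case for naive parallel thinning: isolated 2x2 blocks survive
  blocks <- matrix(FALSE, 12, 12)
  blocks[2:3, 2:3] <- TRUE; blocks[8:9, 8:9] <- TRUE
  expect_identical(countComponents8(mask(skeletonize(binaryImage(blocks)))), 2L)

  for (seed in 1:5) {
    m <- mask(makeFractalMask(syntheticSpec("random_dots", side = 64,
                                            dotDensity = 0.3, seed = seed)))
    sk <- mask(skeletonize(binaryImage(m)))
    expect_identical(countComponents8(sk), countComponents8(m))
    expect_true(all(m[sk]))
  }
})

test_that("box counting matches closed forms and the exhaustive oracle", {
  sq <- binaryImage(matrix(TRUE, 64, 64))
  bc <- boxCount(sq, c(2, 4, 8, 16, 32, 64))
  expect_equal(bc@counts, c(1024, 256, 64, 16, 4, 1))
  expect_equal(fdValue(bc), 2, tolerance = 1e-12)

  line <- makeFractalMask(syntheticSpec("line", side = 64))
  bc <- boxCount(line, c(2, 4, 8, 16, 32, 64))
  expect_equal(bc@counts, c(32, 16, 8, 4, 2, 1))
  expect_equal(fdValue(bc), 1, tolerance = 1e-12)

  carpet <- makeFractalMask(syntheticSpec("sierpinski_carpet", depth = 4, side = 81))
  bc <- boxCount(carpet, c(1, 3, 9, 27, 81))
  expect_equal(bc@counts, c(4096, 512, 64, 8, 1))
  expect_equal(fdValue(bc), log(8) / log(3), tolerance = 1e-12)
  expect_equal(bc@rSquared, 1, tolerance = 1e-12)

  # partial edge boxes are counted: default sizes on a 100 px raster
  m <- mask(makeFractalMask(syntheticSpec("random_dots", side = 100,
                                          dotDensity = 0.15, seed = 21)))
  bc <- boxCount(binaryImage(m))
  expect_equal(unname(bc@counts), unname(oracleBoxCount(m, bc@sizes)))

  # monotone when one size divides another
  expect_true(all(diff(boxCount(binaryImage(m), c(2, 4, 8, 16, 32))@counts) < 0))

  expect_error(boxCount(binaryImage(matrix(FALSE, 10, 10)), c(2, 4)), "degenerate")
  expect_error(boxCount(sq, 4), "two distinct")
  expect_error(boxCount(sq, c(2, 128)), "exceed")
})

test_that("the full pipeline is deterministic and rejects degenerate regions", {
  img <- makeTrabecularTexture(syntheticSpec("fbm_texture", side = 120,
                                             hurst = 0.5, seed = 5))
  roi <- roiSpec("ROI2", 10, 10, 100)
  r1 <- computeFD(img, roi, keepIntermediates = TRUE)
  r2 <- computeFD(img, roi)
  expect_identical(fdValue(r1), fdValue(r2))
  expect_identical(r1@boxcount@counts, r2@boxcount@counts)
  expect_gt(fdValue(r1), 0)
  expect_lt(fdValue(r1), 2)
  expect_named(r1@intermediates,
               c("roi", "blurred", "corrected", "binary", "opened", "skeleton"))
  expect_length(r2@intermediates, 0)

  flat <- grayImage(matrix(77, 120, 120))
  expect_error(computeFD(flat, roi), "degenerate|no trabecular")

  expect_error(computeFD(img, roiSpec("r", 0, 0, 50)),
               "box sizes must not exceed the ROI")
})
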