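wl6 <- seq(400, 1000, length.out = 6)

refFrames <- function(rows = 4, cols = 4) {
  gain <- seq(800, 1200, length.out = 6)
  dark <- rep(100, 6)
  list(white = HyperCube(aperm(array(gain + dark, c(6, rows, cols)),
                               c(2, 3, 1)), wl6),
       dark = HyperCube(aperm(array(dark, c(6, rows, cols)), c(2, 3, 1)),
                        wl6))
}

test_that("calibration closure: white gives 1, dark gives 0, midpoint 0.5", {
  f <- refFrames()
  mid <- HyperCube((f$white@data + f$dark@data) / 2, wl6)
  expect_true(all(abs(calibrate(f$white, f$white, f$dark)@data - 1) < 1e-12))
  expect_true(all(abs(calibrate(f$dark, f$white, f$dark)@data - 0) < 1e-12))
  expect_true(all(abs(calibrate(mid, f$white, f$dark)@data - 0.5) < 1e-12))
})

test_that("per-band vector frames agree with full-cube frames", {
  f <- refFrames()
  raw <- makeToyCube(4, 4, 6, seed = 3, scale = "digital_number")
  raw@data <- raw@data * 500 + 300
  a <- calibrate(raw, f$white, f$dark)
  b <- calibrate(raw, white = f$white@data[1, 1, ],
                 dark = f$dark@data[1, 1, ])
  expect_equal(a@data, b@data)
  expect_equal(a@scale, "reflectance")
})

test_that("calibration is invariant to a common per-band gain rescaling", {
  f <- refFrames()
  raw <- makeToyCube(4, 4, 6, seed = 4)
  raw@data <- raw@data * 400 + 200
  base <- calibrate(raw, f$white, f$dark)@data
  g <- seq(2, 5, length.out = 6)
  scaleCube <- function(cube) {
    cube@data <- sweep(cube@data, 3, g, `*`)
    cube
  }
  rescaled <- calibrate(scaleCube(raw), scaleCube(f$white),
                        scaleCube(f$dark))@data
  expect_equal(rescaled, base, tolerance = 1e-12)
})

test_that("degenerate denominators become NA, are counted, and warn", {
  f <- refFrames(2, 2)
  f$white@data[1, 1, 1] <- f$dark@data[1, 1, 1]  # one degenerate pixel
  raw <- HyperCube(f$white@data * 0.9 + 50, wl6)
  w <- capture_warnings(out <- calibrate(raw, f$white, f$dark))
  expect_match(w, "degenerate", all = FALSE)
  expect_true(is.na(out@data[1, 1, 1]))
  expect_equal(out@header$degenerate_pixels, 1L)
  expect_equal(sum(is.na(out@data)), 1L)
})

test_that("wavelength-axis mismatch between cube and frames errors", {
  f <- refFrames()
  raw <- makeToyCube(4, 4, 6)
  raw@wavelengths <- wl6 + 5
  expect_error(calibrate(raw, f$white, f$dark), "wavelength")
})

test_that("ROI cropping honours 0-based half-open bounds", {
  cube <- makeToyCube(8, 8, 5, seed = 5)
  expect_equal(cropROI(cube, ROI(0, 8, 0, 8))@data, cube@data)
  small <- cropROI(cube, ROI(2, 5, 1, 7))
  expect_equal(dim(small), c(3L, 6L, 5L))
  expect_equal(small@data[1, 1, ], cube@data[3, 2, ])
  one <- cropROI(cube, ROI(4, 5, 4, 5))
  expect_equal(meanSpectrum(one)@values, cube@data[5, 5, ])
  expect_error(cropROI(cube, ROI(0, 9, 0, 8)), "exceeds")
  expect_error(ROI(3, 3, 0, 2), "non-empty")
})

test_that("mean spectrum averages pixels and skips missing values", {
  v <- seq(0.1, 0.6, by = 0.1)
  cube <- HyperCube(aperm(array(v, c(6, 3, 2)), c(2, 3, 1)), wl6,
                    scale = "reflectance")
  expect_equal(meanSpectrum(cube)@values, v)
  two <- HyperCube(array(c(0.2, 0.4), c(2, 1, 1)), 500,
                   scale = "reflectance")
  expect_equal(meanSpectrum(two)@values, 0.3)
  ## brute-force oracle on a random cube
  rc <- makeToyCube(5, 5, 7, seed = 6)
  oracle <- vapply(1:7, function(b) {
    acc <- 0
    for (i in 1:5) for (j in 1:5) acc <- acc + rc@data[i, j, b]
    acc / 25
  }, numeric(1))
  expect_equal(meanSpectrum(rc)@values, oracle)
  ## NA exclusion and the all-missing error
  rc@data[1, 1, 2] <- NA
  expect_equal(meanSpectrum(rc)@values[2],
               mean(rc@data[, , 2], na.rm = TRUE))
  rc@data[, , 3] <- NA
  expect_error(meanSpectrum(rc), "band.*3")
})

test_that("cropping to the full extent leaves the mean spectrum unchanged", {
  cube <- makeToyCube(6, 7, 4, seed = 11)
  expect_equal(meanSpectrum(cropROI(cube, ROI(0, 6, 0, 7)))@values,
               meanSpectrum(cube)@values)
})

test_that("spatial mean filter matches a brute-force window average", {
  cube <- makeToyCube(6, 6, 2, seed = 12)
  sm <- spatialMeanFilter(cube, 5L)
  oracle <- function(i, j, b) {
    ri <- max(1, i - 2):min(6, i + 2)
    rj <- max(1, j - 2):min(6, j + 2)
    mean(cube@data[ri, rj, b])
  }
  for (pt in list(c(1, 1), c(3, 4), c(6, 6)))
    expect_equal(sm@data[pt[1], pt[2], 1], oracle(pt[1], pt[2], 1))
  expect_error(spatialMeanFilter(cube, 4L), "odd")
})
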