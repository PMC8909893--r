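smallParams <- function(seed = 42, ...) {
  simulationParams(n_samples = 8, n_bands = 30, cube_rows = 6,
                   cube_cols = 6, seed = seed, ...)
}

test_that("identical seeds give identical datasets", {
  a <- simulateGingerDataset(smallParams())
  b <- simulateGingerDataset(smallParams())
  expect_identical(spectraMatrix(a), spectraMatrix(b))
  expect_identical(as.data.frame(colData(a)), as.data.frame(colData(b)))
  c <- simulateGingerDataset(smallParams(seed = 43))
  expect_false(identical(spectraMatrix(a), spectraMatrix(c)))
  ## the cube-retaining and streaming paths draw the same samples
  s <- simulateGingerSamples(smallParams())
  expect_equal(s$reference$ratio, colData(a)$ratio)
})

test_that("the default configuration mirrors the study design", {
  p <- simulationParams()
  expect_equal(p@n_samples, 89L)
  expect_equal(p@n_bands, 204L)
  wl <- simulationWavelengths(p)
  expect_equal(length(wl), 204L)
  expect_lt(wl[1], 400)
  expect_gt(wl[204], 1000)
  expect_equal(diff(range(diff(wl))), 0, tolerance = 1e-9)
})

test_that("noise-free configuration recovers true reflectance exactly", {
  p <- smallParams(scatter_multiplicative_sd = 0, scatter_additive_sd = 0,
                   pixel_noise_sd = 0)
  ds <- simulateGingerDataset(p)
  expect_equal(spectraMatrix(ds),
               metadata(ds)$true_reflectance, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("calibration of stored frames recovers reflectance within noise", {
  ## unit multiplicative / zero additive scatter, pixel noise only:
  ## the ROI mean must sit within 3 pixel-noise SDs (of the mean) per band
  p <- simulationParams(n_samples = 6, n_bands = 25, cube_rows = 16,
                        cube_cols = 16, seed = 7,
                        scatter_multiplicative_sd = 0,
                        scatter_additive_sd = 0, pixel_noise_sd = 0.05)
  sim <- simulateGingerSamples(p)
  se <- 0.05 / sqrt(16 * 16)
  for (s in sim$samples) {
    refl <- calibrate(s$raw_cube, s$white_frame, s$dark_frame)
    m <- meanSpectrum(refl)@values
    expect_true(all(abs(m - s$true_reflectance) < 3 * se))
  }
})

test_that("reference chemistry is internally consistent and positive", {
  sim <- simulateGingerSamples(smallParams())
  ref <- sim$reference
  expect_true(all(ref$gingerol > 0 & ref$shogaol > 0))
  expect_equal(ref$ratio, ref$gingerol / ref$shogaol)
  cube <- sim$samples[[1]]$raw_cube
  expect_equal(dim(cube), c(6L, 6L, 30L))
})

test_that("default concentration law spans the intended ratio range", {
  ds <- simulateGingerDataset(simulationParams(cube_rows = 2,
                                               cube_cols = 2))
  r <- ratios(ds)
  expect_gt(max(r), 2.5)
  expect_lt(min(r), 1)
  expect_true(all(is.finite(r) & r > 0))
  expect_gt(median(r), 1)
  expect_lt(median(r), 2.5)
})

test_that("reference table round-trips and rejects duplicates", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "ref.csv")
  tab <- data.frame(sample_id = c("a", "b", "c"),
                    gingerol = c(2.0, 8.123456, 5.5),
                    shogaol = c(1.0, 4.2, 3.3))
  tab$ratio <- tab$gingerol / tab$shogaol
  writeReferenceTable(tab, path)
  expect_equal(tab$ratio[1], 2.0)
  lines <- readLines(path)
  expect_length(lines, 4L)  # header + 3 rows
  back <- readReferenceTable(path)
  expect_equal(round(back$gingerol, 6), round(tab$gingerol, 6))
  expect_equal(round(back$ratio, 6), round(tab$ratio, 6))
  tab$sample_id[2] <- "a"
  expect_error(writeReferenceTable(tab, path), "duplicate.*a")
})

test_that("simulation parameters survive a YAML round trip", {
  p <- smallParams(scatter_additive_sd = 0.017)
  path <- file.path(withr::local_tempdir(), "params.yaml")
  writeSimulationParams(p, path)
  q <- readSimulationParams(path)
  expect_equal(q@n_samples, p@n_samples)
  expect_equal(q@scatter_additive_sd, 0.017)
  expect_equal(q@constituent_bands, p@constituent_bands)
  ## same params, same data
  expect_equal(spectraMatrix(simulateGingerDataset(q)),
               spectraMatrix(simulateGingerDataset(p)))
})

test_that("an exported simulation reloads through the ENVI front end", {
  p <- simulationParams(n_samples = 2, n_bands = 12, cube_rows = 3,
                        cube_cols = 4, seed = 9)
  dir <- file.path(withr::local_tempdir(), "sim")
  exportSimulation(p, dir, data_type = 5L)
  expect_true(file.exists(file.path(dir, "reference.csv")))
  sim <- simulateGingerSamples(p)
  raw <- readENVI(file.path(dir, "raw_S001.hdr"))
  expect_equal(raw@data, sim$samples[[1]]$raw_cube@data)
  white <- readENVI(file.path(dir, "white.hdr"))
  refl <- calibrate(raw, white = drop(white@data[1, 1, ]),
                    dark = drop(readENVI(file.path(dir, "dark.hdr"))@data[1, 1, ]))
  expect_equal(dim(refl), c(3L, 4L, 12L))
})

test_that("parameter validation rejects degenerate configurations", {
  expect_error(simulationParams(n_bands = 3), "at least 4")
  expect_error(simulationParams(pixel_noise_sd = -0.1), "non-negative")
  expect_error(simulationParams(wavelength_start = 1000,
                                wavelength_end = 400), "increasing")
})

test_that("noise-free spectra identify the constituent concentrations", {
  ## with no noise and non-collinear band sets, a 2-LV PLSR recovers the
  ## ratio-relevant concentrations essentially exactly (the spectra are
  ## linear in the concentrations by construction)
  p <- simulationParams(n_samples = 40, n_bands = 60, cube_rows = 2,
                        cube_cols = 2, seed = 11,
                        scatter_multiplicative_sd = 0,
                        scatter_additive_sd = 0, pixel_noise_sd = 0,
                        concentration_sdlog = c(gingerol = 0.25,
                                                shogaol = 0.08))
  ds <- simulateGingerDataset(p)
  X <- spectraMatrix(ds)
  for (const in c("gingerol", "shogaol")) {
    y <- colData(ds)[[const]]
    m <- fitPLSR(X, y, n_lvs = 2L)
    expect_gt(rSquared(y, m@fitted), 0.999, label = const)
  }
})
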