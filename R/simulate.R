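## Synthetic hyperspectral ginger samples. The forward model mimics what
## the camera sees: a smooth bright powder baseline with Beer-Lambert-style
## Gaussian absorption bands scaled by the 6-gingerol and 6-shogaol
## concentrations, per-sample multiplicative/additive scatter (packing and
## particle-size effects that survive ROI averaging), a band-dependent
## sensor gain and dark level, and per-pixel shot-like noise.

#' SimulationParams: configuration of the synthetic-cube generator
#'
#' Defaults emulate the instrument and study design being modelled:
#' 89 samples, 204 bands from 397.32 to 1003.58 nm, 64 x 64 pixel cubes,
#' and log-normal constituent concentrations whose ratio spans roughly
#' 0.5-4.
#'
#' @slot n_samples sample count (default 89).
#' @slot n_bands band count (default 204, minimum 4).
#' @slot wavelength_start,wavelength_end axis endpoints in nm (defaults
#'   397.32 and 1003.58; uniform spacing).
#' @slot cube_rows,cube_cols spatial cube shape per sample (default 64).
#' @slot constituent_bands named list (`gingerol`, `shogaol`) of matrices
#'   with columns `center` (nm), `width` (nm, Gaussian sigma) and `weight`
#'   (peak reflectance depression per mg/g).
#' @slot concentration_meanlog,concentration_sdlog log-normal law of the
#'   two concentrations (mg/g), named `gingerol` and `shogaol`.
#' @slot scatter_multiplicative_sd,scatter_additive_sd per-sample scatter
#'   SDs (unitless; reflectance units).
#' @slot pixel_noise_sd per-pixel noise SD in reflectance units (applied on
#'   the DN scale as `pixel_noise_sd * gain`).
#' @slot seed RNG seed.
#' @seealso [simulationParams()], [simulateGingerDataset()]
#' @export
setClass("SimulationParams",
  representation(n_samples = "integer", n_bands = "integer",
                 wavelength_start = "numeric", wavelength_end = "numeric",
                 cube_rows = "integer", cube_cols = "integer",
                 constituent_bands = "list",
                 concentration_meanlog = "numeric",
                 concentration_sdlog = "numeric",
                 scatter_multiplicative_sd = "numeric",
                 scatter_additive_sd = "numeric",
                 pixel_noise_sd = "numeric", seed = "integer"))

setValidity("SimulationParams", function(object) {
  msg <- character()
  if (object@n_bands < 4L) msg <- c(msg, "n_bands must be at least 4")
  if (object@wavelength_end <= object@wavelength_start)
    msg <- c(msg, "wavelength axis must be increasing")
  if (object@n_samples < 1L) msg <- c(msg, "n_samples must be positive")
  if (object@cube_rows < 1L || object@cube_cols < 1L)
    msg <- c(msg, "cube shape must be positive")
  sds <- c(object@scatter_multiplicative_sd, object@scatter_additive_sd,
           object@pixel_noise_sd)
  if (any(sds < 0)) msg <- c(msg, "noise SDs must be non-negative")
  for (nm in c("gingerol", "shogaol")) {
    b <- object@constituent_bands[[nm]]
    if (is.null(b) || !is.matrix(b) ||
        !all(c("center", "width", "weight") %in% colnames(b)))
      msg <- c(msg, sprintf(
        "constituent_bands$%s must be a matrix with center/width/weight",
        nm))
  }
  if (!all(c("gingerol", "shogaol") %in%
           names(object@concentration_meanlog)))
    msg <- c(msg, "concentration_meanlog needs gingerol and shogaol")
  if (any(object@concentration_sdlog < 0))
    msg <- c(msg, "concentration_sdlog must be non-negative")
  if (length(msg)) msg else TRUE
})

.bandMatrix <- function(...) {
  m <- rbind(...)
  colnames(m) <- c("center", "width", "weight")
  m
}

.defaultConstituentBands <- function() list(
  gingerol = .bandMatrix(c(450, 30, 0.010), c(670, 45, 0.014),
                         c(910, 55, 0.011)),
  shogaol = .bandMatrix(c(520, 35, 0.012), c(760, 50, 0.016),
                        c(970, 60, 0.010)))

#' Construct simulation parameters
#'
#' @param n_samples,n_bands,wavelength_start,wavelength_end,cube_rows,cube_cols
#'   see [SimulationParams-class].
#' @param constituent_bands named list of band matrices; see
#'   [SimulationParams-class]. The default places three non-collinear
#'   Gaussian bands per constituent across the Vis-NIR range.
#' @param concentration_meanlog,concentration_sdlog log-normal
#'   concentration law (mg/g). The defaults (gingerol: meanlog log(7.5),
#'   sdlog 0.5; shogaol: meanlog log(5), sdlog 0.15) give a
#'   gingerol:shogaol ratio spanning roughly 0.5-4, so limits of detection
#'   near 0.6-1.0 fall inside the data range.
#' @param scatter_multiplicative_sd,scatter_additive_sd,pixel_noise_sd
#'   noise levels; see [SimulationParams-class].
#' @param seed RNG seed (default 1).
#' @return A validated [SimulationParams-class].
#' @export
simulationParams <- function(n_samples = 89L, n_bands = 204L,
                             wavelength_start = 397.32,
                             wavelength_end = 1003.58,
                             cube_rows = 64L, cube_cols = 64L,
                             constituent_bands = .defaultConstituentBands(),
                             concentration_meanlog =
                               c(gingerol = log(7.5), shogaol = log(5)),
                             concentration_sdlog =
                               c(gingerol = 0.5, shogaol = 0.15),
                             scatter_multiplicative_sd = 0.08,
                             scatter_additive_sd = 0.03,
                             pixel_noise_sd = 0.02,
                             seed = 1L) {
  new("SimulationParams", n_samples = as.integer(n_samples),
      n_bands = as.integer(n_bands),
      wavelength_start = wavelength_start,
      wavelength_end = wavelength_end,
      cube_rows = as.integer(cube_rows), cube_cols = as.integer(cube_cols),
      constituent_bands = constituent_bands,
      concentration_meanlog = concentration_meanlog,
      concentration_sdlog = concentration_sdlog,
      scatter_multiplicative_sd = scatter_multiplicative_sd,
      scatter_additive_sd = scatter_additive_sd,
      pixel_noise_sd = pixel_noise_sd, seed = as.integer(seed))
}

setMethod("show", "SimulationParams", function(object) {
  cat(sprintf(
    "SimulationParams: %d samples, %d bands (%.2f-%.2f nm), %d x %d cubes, seed %d\n",
    object@n_samples, object@n_bands, object@wavelength_start,
    object@wavelength_end, object@cube_rows, object@cube_cols,
    object@seed))
})

#' @rdname simulationParams
#' @param params a [SimulationParams-class].
#' @export
simulationWavelengths <- function(params)
  seq(params@wavelength_start, params@wavelength_end,
      length.out = params@n_bands)

## instrument response: smooth bright-powder baseline, band-dependent gain
## and dark level
.simBaseline <- function(wl)
  0.50 + 3e-4 * (wl - 400) + 0.03 * sin((wl - 400) / 600 * pi)
.simGain <- function(wl)
  3000 * (0.6 + 0.4 * exp(-((wl - 650) / 250)^2))
.simDark <- function(wl) 96 + 0.01 * (wl - 400)

## per-mg/g absorption profile of one constituent
.absorptionProfile <- function(bands, wl) {
  prof <- numeric(length(wl))
  for (b in seq_len(nrow(bands)))
    prof <- prof + bands[b, "weight"] *
      exp(-(wl - bands[b, "center"])^2 / (2 * bands[b, "width"]^2))
  prof
}

## strictly positive draws (rejection; the log-normal default never rejects)
.drawPositive <- function(n, meanlog, sdlog) {
  x <- rlnorm(n, meanlog, sdlog)
  while (any(x <= 0)) x[x <= 0] <- rlnorm(sum(x <= 0), meanlog, sdlog)
  x
}

## one sample's draws and cube, advancing the RNG state deterministically
.simOneSample <- function(params, wl, prof_g, prof_s, baseline, gain,
                          dark) {
  cg <- .drawPositive(1, params@concentration_meanlog["gingerol"],
                      params@concentration_sdlog["gingerol"])
  cs <- .drawPositive(1, params@concentration_meanlog["shogaol"],
                      params@concentration_sdlog["shogaol"])
  r <- pmin(pmax(baseline - cg * prof_g - cs * prof_s, 0.02), 0.98)
  a <- rnorm(1, 1, params@scatter_multiplicative_sd)
  while (a <= 0) a <- rnorm(1, 1, params@scatter_multiplicative_sd)
  b <- rnorm(1, 0, params@scatter_additive_sd)
  npix <- params@cube_rows * params@cube_cols
  dn <- outer(rep(1, npix), gain * (a * r + b) + dark)
  if (params@pixel_noise_sd > 0)
    dn <- dn + rnorm(npix * params@n_bands) *
      rep(params@pixel_noise_sd * gain, each = npix)
  list(cube = HyperCube(array(dn, c(params@cube_rows, params@cube_cols,
                                    params@n_bands)), wl),
       true_reflectance = r, gingerol = unname(cg), shogaol = unname(cs),
       a = a, b = b)
}

#' Generate synthetic ginger samples with raw cubes
#'
#' Produces the full simulated acquisition for each sample: a raw
#' digital-number [HyperCube-class], the shared white and dark reference
#' frames (per-band vectors, `white = gain + dark`, `dark` alone), the
#' sample's true reflectance spectrum and its reference chemistry.
#' Calibrating the raw cube with the stored frames recovers
#' `a * r + b` plus pixel noise, and the noise-free configuration recovers
#' `r` exactly.
#'
#' Deterministic for a fixed seed. Memory scales with
#' `n_samples * cube_rows * cube_cols * n_bands`; use
#' [simulateGingerDataset()] for the streaming spectra-only path.
#'
#' @param params a [SimulationParams-class].
#' @return list with `samples` (list of per-sample lists: `raw_cube`,
#'   `white_frame`, `dark_frame`, `true_reflectance`, `gingerol_conc`,
#'   `shogaol_conc`, `ratio`), `reference` (data.frame), `wavelengths`,
#'   and `params`.
#' @export
simulateGingerSamples <- function(params = simulationParams()) {
  validObject(params)
  wl <- simulationWavelengths(params)
  baseline <- .simBaseline(wl)
  gain <- .simGain(wl)
  dark <- .simDark(wl)
  prof_g <- .absorptionProfile(params@constituent_bands$gingerol, wl)
  prof_s <- .absorptionProfile(params@constituent_bands$shogaol, wl)
  ids <- sprintf("S%03d", seq_len(params@n_samples))
  samples <- withr::with_seed(params@seed, lapply(
    seq_len(params@n_samples), function(i) {
      s <- .simOneSample(params, wl, prof_g, prof_s, baseline, gain, dark)
      list(sample_id = ids[i], raw_cube = s$cube, white_frame = gain + dark,
           dark_frame = dark, true_reflectance = s$true_reflectance,
           gingerol_conc = s$gingerol, shogaol_conc = s$shogaol,
           ratio = s$gingerol / s$shogaol)
    }))
  reference <- data.frame(
    sample_id = ids,
    gingerol = vapply(samples, `[[`, numeric(1), "gingerol_conc"),
    shogaol = vapply(samples, `[[`, numeric(1), "shogaol_conc"),
    ratio = vapply(samples, `[[`, numeric(1), "ratio"))
  list(samples = samples, reference = reference, wavelengths = wl,
       params = params)
}

#' Simulate a calibrated spectral dataset
#'
#' Runs the generator sample by sample through the standard extraction
#' path — reflectance calibration against the white/dark frames, optional
#' ROI crop, ROI mean spectrum — without retaining the raw cubes, and
#' assembles the result into a [SpectralDataset-class] paired with the
#' reference chemistry. Identical seeds give identical datasets, and the
#' spectra equal those obtained from [simulateGingerSamples()] plus
#' [calibrate()]/[meanSpectrum()].
#'
#' @param params a [SimulationParams-class].
#' @param roi optional [ROI-class] applied before averaging (default: the
#'   full cube).
#' @return A [SpectralDataset-class]; `metadata()` carries `params` and
#'   the per-sample `true_reflectance` matrix.
#' @export
simulateGingerDataset <- function(params = simulationParams(),
                                  roi = NULL) {
  validObject(params)
  wl <- simulationWavelengths(params)
  baseline <- .simBaseline(wl)
  gain <- .simGain(wl)
  dark <- .simDark(wl)
  prof_g <- .absorptionProfile(params@constituent_bands$gingerol, wl)
  prof_s <- .absorptionProfile(params@constituent_bands$shogaol, wl)
  n <- params@n_samples
  X <- matrix(NA_real_, n, params@n_bands)
  Rtrue <- matrix(NA_real_, n, params@n_bands)
  cg <- cs <- numeric(n)
  withr::with_seed(params@seed, for (i in seq_len(n)) {
    s <- .simOneSample(params, wl, prof_g, prof_s, baseline, gain, dark)
    refl <- calibrate(s$cube, white = gain + dark, dark = dark)
    if (!is.null(roi)) refl <- cropROI(refl, roi)
    X[i, ] <- meanSpectrum(refl)@values
    Rtrue[i, ] <- s$true_reflectance
    cg[i] <- s$gingerol; cs[i] <- s$shogaol
  })
  reference <- data.frame(sample_id = sprintf("S%03d", seq_len(n)),
                          gingerol = cg, shogaol = cs, ratio = cg / cs)
  out <- SpectralDataset(X, wl, reference, treatment = "raw")
  metadata(out)$params <- params
  metadata(out)$true_reflectance <- Rtrue
  out
}

#' Write the reference chemistry table
#'
#' One row per sample with columns `sample_id`, `gingerol`, `shogaol`,
#' `ratio`; values round-trip losslessly at the stored precision.
#'
#' @param x a [SpectralDataset-class], the result of
#'   [simulateGingerSamples()], or a data.frame with the four columns.
#' @param path output CSV path.
#' @return Invisibly, the data.frame written.
#' @export
writeReferenceTable <- function(x, path) {
  tab <- if (is(x, "SpectralDataset"))
    as.data.frame(colData(x))[, c("sample_id", "gingerol", "shogaol",
                                  "ratio")]
  else if (is.list(x) && !is.null(x$reference)) x$reference
  else as.data.frame(x)
  stopifnot(all(c("sample_id", "gingerol", "shogaol", "ratio") %in%
                names(tab)))
  if (!nrow(tab)) stop("no samples to write")
  if (anyDuplicated(tab$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(tab$sample_id[duplicated(tab$sample_id)]),
               collapse = ", "))
  write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(tab)
}

#' @rdname writeReferenceTable
#' @export
readReferenceTable <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "gingerol", "shogaol", "ratio") %in%
                names(tab)))
  tab
}

#' Persist simulation parameters as YAML
#'
#' @param params a [SimulationParams-class].
#' @param path YAML file path.
#' @return `writeSimulationParams` invisibly returns `path`;
#'   `readSimulationParams` returns the reconstructed
#'   [SimulationParams-class].
#' @export
writeSimulationParams <- function(params, path) {
  lst <- list(
    n_samples = params@n_samples, n_bands = params@n_bands,
    wavelength_start = params@wavelength_start,
    wavelength_end = params@wavelength_end,
    cube_rows = params@cube_rows, cube_cols = params@cube_cols,
    constituent_bands = lapply(params@constituent_bands, function(m)
      lapply(seq_len(nrow(m)), function(i) as.list(m[i, ]))),
    concentration_meanlog = as.list(params@concentration_meanlog),
    concentration_sdlog = as.list(params@concentration_sdlog),
    scatter_multiplicative_sd = params@scatter_multiplicative_sd,
    scatter_additive_sd = params@scatter_additive_sd,
    pixel_noise_sd = params@pixel_noise_sd, seed = params@seed)
  yaml::write_yaml(lst, path, precision = 15L)
  invisible(path)
}

#' @rdname writeSimulationParams
#' @export
readSimulationParams <- function(path) {
  lst <- yaml::read_yaml(path)
  bands <- lapply(lst$constituent_bands, function(rows)
    do.call(rbind, lapply(rows, function(r)
      .bandMatrix(c(r$center, r$width, r$weight)))))
  simulationParams(
    n_samples = lst$n_samples, n_bands = lst$n_bands,
    wavelength_start = lst$wavelength_start,
    wavelength_end = lst$wavelength_end,
    cube_rows = lst$cube_rows, cube_cols = lst$cube_cols,
    constituent_bands = bands,
    concentration_meanlog = unlist(lst$concentration_meanlog),
    concentration_sdlog = unlist(lst$concentration_sdlog),
    scatter_multiplicative_sd = lst$scatter_multiplicative_sd,
    scatter_additive_sd = lst$scatter_additive_sd,
    pixel_noise_sd = lst$pixel_noise_sd, seed = lst$seed)
}

#' Export a simulation to disk as ENVI cubes
#'
#' Writes one ENVI `.hdr`/`.dat` pair per sample plus single-row white and
#' dark reference cubes, the reference CSV and the parameters as YAML —
#' the on-disk layout the calibration front end consumes.
#'
#' @param params a [SimulationParams-class].
#' @param dir output directory (created if needed).
#' @param interleave,data_type passed to [writeENVI()].
#' @return Invisibly, the output directory.
#' @export
exportSimulation <- function(params, dir, interleave = "bil",
                             data_type = 4L) {
  sim <- simulateGingerSamples(params)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in sim$samples)
    writeENVI(s$raw_cube, file.path(dir, paste0("raw_", s$sample_id)),
              interleave = interleave, data_type = data_type)
  wl <- sim$wavelengths
  frame <- function(v) HyperCube(array(v, c(1L, 1L, length(v))), wl)
  writeENVI(frame(sim$samples[[1]]$white_frame), file.path(dir, "white"),
            interleave = interleave, data_type = data_type)
  writeENVI(frame(sim$samples[[1]]$dark_frame), file.path(dir, "dark"),
            interleave = interleave, data_type = data_type)
  writeReferenceTable(sim$reference, file.path(dir, "reference.csv"))
  writeSimulationParams(params, file.path(dir, "params.yaml"))
  invisible(dir)
}
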