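#' ROI: a rectangular region of interest
#'
#' Pixel coordinates are 0-based, half-open intervals: `ROI(0, 10, 0, 10)`
#' covers the first ten rows and columns. This mirrors the manual square ROI
#' drawn over the powder sample before spectrum extraction.
#'
#' @slot row_start,row_end,col_start,col_end integer pixel bounds,
#'   half-open.
#' @export
setClass("ROI", representation(row_start = "integer", row_end = "integer",
                               col_start = "integer", col_end = "integer"))

setValidity("ROI", function(object) {
  if (object@row_start < 0L || object@col_start < 0L)
    return("ROI bounds must be non-negative")
  if (object@row_end <= object@row_start ||
      object@col_end <= object@col_start)
    return("ROI must be non-empty (end > start, half-open)")
  TRUE
})

#' @rdname ROI-class
#' @param row_start,row_end,col_start,col_end 0-based half-open pixel
#'   bounds.
#' @export
ROI <- function(row_start, row_end, col_start, col_end)
  new("ROI", row_start = as.integer(row_start),
      row_end = as.integer(row_end), col_start = as.integer(col_start),
      col_end = as.integer(col_end))

setMethod("show", "ROI", function(object) {
  cat(sprintf("ROI: rows [%d, %d), cols [%d, %d)\n", object@row_start,
              object@row_end, object@col_start, object@col_end))
})

.referenceFrame <- function(frame, d, wl, what) {
  if (is(frame, "HyperCube")) {
    if (length(frame@wavelengths) != length(wl) ||
        any(abs(frame@wavelengths - wl) > 1e-9))
      stop(what, " frame wavelength axis does not match the raw cube")
    fd <- dim(frame@data)
    if (!all(fd == d))
      stop(sprintf("%s frame is %d x %d x %d but raw cube is %d x %d x %d",
                   what, fd[1], fd[2], fd[3], d[1], d[2], d[3]))
    frame@data
  } else if (is.numeric(frame) && length(frame) == d[3]) {
    ## per-band reference (e.g. dark level recorded inside the sensor)
    aperm(array(frame, c(d[3], d[1], d[2])), c(2, 3, 1))
  } else {
    stop(what, " frame must be a HyperCube matching the raw cube or a ",
         "per-band numeric vector")
  }
}

#' Reflectance calibration against white and dark references
#'
#' Converts raw digital numbers to relative reflectance per pixel and band:
#' \deqn{I_c = (I_{raw} - I_{dark}) / (I_{white} - I_{dark})}
#' removing the sensor dark current and the illumination/gain profile. The
#' white tile's nominal 99% reflectance is not divided out; the constant is
#' absorbed by the downstream regression.
#'
#' Pixels where the denominator magnitude falls below `eps` are set to `NA`
#' and counted in the output's `header$degenerate_pixels`; if they exceed 1%
#' of all pixel-band values a warning reports the count.
#'
#' @param raw a digital-number [HyperCube-class].
#' @param white,dark reference frames: either `HyperCube`s with the same
#'   dimensions and wavelength axis as `raw`, or per-band numeric vectors.
#' @param eps degenerate-denominator threshold (DN units).
#' @return A reflectance-scale [HyperCube-class].
#' @examples
#' wl <- seq(400, 1000, length.out = 5)
#' raw <- HyperCube(array(500, c(2, 2, 5)), wl)
#' refl <- calibrate(raw, white = rep(900, 5), dark = rep(100, 5))
#' range(refl@data)  # (500-100)/(900-100) = 0.5
#' @export
setGeneric("calibrate",
           function(raw, white, dark, eps = 1e-10)
             standardGeneric("calibrate"))

#' @rdname calibrate
#' @export
setMethod("calibrate", "HyperCube", function(raw, white, dark,
                                             eps = 1e-10) {
  d <- dim(raw@data)
  wl <- raw@wavelengths
  Iw <- .referenceFrame(white, d, wl, "white")
  Id <- .referenceFrame(dark, d, wl, "dark")
  den <- Iw - Id
  if (mean(den > 0) < 0.99)
    warning("white <= dark on more than 1% of pixels; reference frames ",
            "are suspect")
  bad <- abs(den) < eps
  num <- raw@data - Id
  out <- num / den
  n_bad <- sum(bad)
  if (n_bad > 0) out[bad] <- NA_real_
  if (n_bad > 0.01 * length(out))
    warning(sprintf("%d pixel values (%.1f%%) had degenerate denominators",
                    n_bad, 100 * n_bad / length(out)))
  hdr <- raw@header
  hdr$degenerate_pixels <- n_bad
  new("HyperCube", data = out, wavelengths = wl, scale = "reflectance",
      header = hdr)
})

#' Crop a cube to a region of interest
#'
#' @param cube a [HyperCube-class].
#' @param roi an [ROI-class] (0-based, half-open pixel bounds).
#' @return A `HyperCube` with spatial shape equal to the ROI extents and an
#'   unchanged band axis.
#' @export
setGeneric("cropROI", function(cube, roi) standardGeneric("cropROI"))

#' @rdname cropROI
#' @export
setMethod("cropROI", signature("HyperCube", "ROI"), function(cube, roi) {
  d <- dim(cube@data)
  if (roi@row_end > d[1] || roi@col_end > d[2])
    stop(sprintf(
      "ROI rows [%d, %d) x cols [%d, %d) exceeds cube extent %d x %d",
      roi@row_start, roi@row_end, roi@col_start, roi@col_end, d[1], d[2]))
  new("HyperCube",
      data = cube@data[(roi@row_start + 1L):roi@row_end,
                       (roi@col_start + 1L):roi@col_end, , drop = FALSE],
      wavelengths = cube@wavelengths, scale = cube@scale,
      header = cube@header)
})

#' ROI mean spectrum
#'
#' Per-band arithmetic mean over all spatial pixels, excluding
#' missing-value (degenerate-calibration) pixels band-wise. This averaging
#' over the ROI suppresses per-pixel random noise before modelling.
#'
#' @param cube a reflectance-scale [HyperCube-class] (typically already
#'   cropped to the ROI).
#' @return A [Spectrum-class].
#' @export
setGeneric("meanSpectrum", function(cube) standardGeneric("meanSpectrum"))

#' @rdname meanSpectrum
#' @export
setMethod("meanSpectrum", "HyperCube", function(cube) {
  d <- dim(cube@data)
  m <- matrix(cube@data, nrow = d[1] * d[2], ncol = d[3])
  v <- colMeans(m, na.rm = TRUE)
  empty <- colSums(!is.na(m)) == 0L
  if (any(empty))
    stop("no valid pixels in band(s) ",
         paste(which(empty), collapse = ", "))
  Spectrum(cube@wavelengths, v)
})

#' Spatial mean filter (optional pre-averaging smoother)
#'
#' Per-band moving-average smoothing in the spatial plane with a
#' `width` x `width` window (edges truncated to in-range pixels). This is
#' the image-domain reading of the "mean filter" pre-treatment, applied to
#' the cube before ROI averaging; the canonical pipeline instead applies
#' the one-dimensional [meanFilter()] to the averaged spectra.
#'
#' @param cube a [HyperCube-class].
#' @param width odd window size (e.g. 5 or 9).
#' @return A smoothed `HyperCube`.
#' @export
spatialMeanFilter <- function(cube, width = 5L) {
  stopifnot(is(cube, "HyperCube"))
  if (width %% 2L == 0L) stop("width must be odd")
  h <- (width - 1L) / 2L
  d <- dim(cube@data)
  out <- cube@data
  ## separable box filter with truncated edges: rows then cols, per band
  runmean <- function(M, h) {
    n <- nrow(M)
    cs <- rbind(0, apply(M, 2, cumsum))
    cnt <- pmin(seq_len(n) + h, n) - pmax(seq_len(n) - h, 1L) + 1L
    (cs[pmin(seq_len(n) + h, n) + 1L, , drop = FALSE] -
       cs[pmax(seq_len(n) - h, 1L), , drop = FALSE]) / cnt
  }
  for (b in seq_len(d[3])) {
    M <- runmean(cube@data[, , b], h)
    out[, , b] <- t(runmean(t(M), h))
  }
  new("HyperCube", data = out, wavelengths = cube@wavelengths,
      scale = cube@scale, header = cube@header)
}
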