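## Spectral pre-treatments. Each operates row-wise on a samples x bands
## matrix or on a SpectralDataset (returned with an updated treatment tag);
## all preserve the matrix shape and the wavelength axis.

.applyToSpectra <- function(x, fun, tag) {
  if (is(x, "SpectralDataset")) {
    X <- fun(spectraMatrix(x))
    assay(x, "spectra") <- t(X)
    metadata(x)$treatment <- tag
    validObject(x)
    x
  } else {
    fun(stopIfNotMatrix(x))
  }
}

#' Standard normal variate (SNV)
#'
#' Centres and scales each spectrum to mean 0 and unit standard deviation
#' (sample SD, denominator K-1), removing per-spectrum additive offsets and
#' multiplicative scatter: `snv(a*x + b)` equals `snv(x)` for any `a > 0`.
#'
#' @param x samples x bands matrix or [SpectralDataset-class].
#' @return Same type as `x`, transformed row-wise.
#' @examples
#' snv(rbind(c(1, 2, 3)))  # -1 0 1
#' @export
snv <- function(x) {
  .applyToSpectra(x, function(X) {
    mu <- rowMeans(X)
    s <- apply(X, 1, sd)
    if (any(s == 0))
      stop("zero-SD spectrum in sample(s) ",
           paste(which(s == 0), collapse = ", "))
    (X - mu) / s
  }, "snv")
}

#' MscReference: fitted multiplicative scatter correction state
#'
#' @slot reference band-wise mean spectrum of the training set.
#' @slot slopes,intercepts per-training-sample OLS fits against the
#'   reference.
#' @seealso [mscFit()], [mscApply()]
#' @export
setClass("MscReference",
  representation(reference = "numeric", slopes = "numeric",
                 intercepts = "numeric"))

setValidity("MscReference", function(object) {
  if (any(abs(object@slopes) < 1e-8))
    return("fitted slope ~ 0; MSC reference is degenerate")
  TRUE
})

setMethod("show", "MscReference", function(object) {
  cat(sprintf("MscReference: %d bands, %d training spectra, slopes in [%.3g, %.3g]\n",
              length(object@reference), length(object@slopes),
              min(object@slopes), max(object@slopes)))
})

.mscOls <- function(X, ref) {
  ## per-row OLS of x on (1, ref)
  rc <- ref - mean(ref)
  slopes <- drop(X %*% rc) / sum(rc^2)
  intercepts <- rowMeans(X) - slopes * mean(ref)
  list(slopes = slopes, intercepts = intercepts)
}

#' Multiplicative scatter correction: fit the reference
#'
#' The reference spectrum is the band-wise mean of the *training* spectra
#' only; it is then applied frozen to any split (no information leakage
#' into the test set).
#'
#' @param x_train training samples x bands matrix or
#'   [SpectralDataset-class] (at least 2 samples).
#' @return An [MscReference-class].
#' @export
mscFit <- function(x_train) {
  X <- if (is(x_train, "SpectralDataset")) spectraMatrix(x_train)
       else stopIfNotMatrix(x_train)
  if (nrow(X) < 2L) stop("MSC needs at least 2 training samples")
  ref <- colMeans(X)
  fit <- .mscOls(X, ref)
  new("MscReference", reference = ref, slopes = fit$slopes,
      intercepts = fit$intercepts)
}

#' Multiplicative scatter correction: apply
#'
#' Each spectrum x is regressed on the reference by ordinary least squares,
#' `x ~ intercept + slope * reference`, and corrected as
#' `(x - intercept) / slope`. A spectrum that is an exact affine distortion
#' `a * reference + b` is restored to the reference itself.
#'
#' @param x samples x bands matrix or [SpectralDataset-class].
#' @param ref an [MscReference-class] from [mscFit()].
#' @return Same type as `x`, corrected row-wise.
#' @export
mscApply <- function(x, ref) {
  stopifnot(is(ref, "MscReference"))
  .applyToSpectra(x, function(X) {
    if (ncol(X) != length(ref@reference))
      stop("band count does not match the MSC reference")
    fit <- .mscOls(X, ref@reference)
    if (any(abs(fit$slopes) < 1e-8))
      stop("MSC slope ~ 0 for sample(s) ",
           paste(which(abs(fit$slopes) < 1e-8), collapse = ", "))
    (X - fit$intercepts) / fit$slopes
  }, "msc")
}

#' Moving-average (mean) filter along the band axis
#'
#' Centred moving average of each spectrum with an odd window `width`
#' (MF5 and MF9 in the canonical treatment list; MF11 is also accepted).
#' Edges are handled by truncating the window to in-range bands.
#'
#' @param x samples x bands matrix or [SpectralDataset-class].
#' @param width odd window width, at most the band count.
#' @return Same type as `x`, smoothed row-wise.
#' @export
meanFilter <- function(x, width = 5L) {
  width <- as.integer(width)
  if (width %% 2L == 0L) stop("width must be odd")
  .applyToSpectra(x, function(X) {
    K <- ncol(X)
    if (width > K) stop("width exceeds the band count")
    h <- (width - 1L) %/% 2L
    lo <- pmax(seq_len(K) - h, 1L)
    hi <- pmin(seq_len(K) + h, K)
    cs <- cbind(0, t(apply(X, 1, cumsum)))
    (cs[, hi + 1L, drop = FALSE] - cs[, lo, drop = FALSE]) /
      rep(hi - lo + 1L, each = nrow(X))
  }, paste0("mf", width))
}

#' Savitzky-Golay derivative
#'
#' Row-wise Savitzky-Golay convolution derivative: each output point is the
#' `deriv`-th derivative of a local least-squares polynomial of order
#' `polyorder` fitted over an odd `window` of bands (edge points use
#' one-sided fits). The result is divided by the uniform band spacing raised
#' to `deriv`, yielding per-nm units when the wavelength axis is supplied.
#' Polynomials of degree at most `polyorder` are differentiated exactly.
#'
#' @param x samples x bands matrix or [SpectralDataset-class].
#' @param deriv derivative order, 1 or 2.
#' @param window odd window size, greater than `polyorder` (default 11).
#' @param polyorder local polynomial order (default 2 for the first
#'   derivative, 3 for the second).
#' @param spacing band spacing in nm; defaults to the dataset's wavelength
#'   axis spacing for a `SpectralDataset` and to 1 (per-index derivative)
#'   for a bare matrix.
#' @return Same type as `x`, differentiated row-wise.
#' @export
savgolDerivative <- function(x, deriv = 1L, window = 11L,
                             polyorder = if (deriv == 1L) 2L else 3L,
                             spacing = NULL) {
  deriv <- as.integer(deriv); window <- as.integer(window)
  polyorder <- as.integer(polyorder)
  if (!deriv %in% c(1L, 2L)) stop("deriv must be 1 or 2")
  if (window %% 2L == 0L) stop("window must be odd")
  if (polyorder >= window) stop("polyorder must be less than window")
  if (deriv > polyorder) stop("deriv must not exceed polyorder")
  if (is.null(spacing))
    spacing <- if (is(x, "SpectralDataset")) bandSpacing(wavelengths(x))
               else 1
  .applyToSpectra(x, function(X) {
    if (window > ncol(X)) stop("window exceeds the band count")
    t(apply(X, 1, signal::sgolayfilt, p = polyorder, n = window,
            m = deriv, ts = spacing))
  }, paste0("sg", deriv))
}

#' Canonical pre-treatment list
#'
#' The eight pre-treatment variants of the canonical model grid: untreated
#' averaged spectra plus SNV, MSC, moving-average filters of widths 5, 9
#' and 11, and first- and second-derivative Savitzky-Golay.
#'
#' @return character vector of treatment tags.
#' @seealso [applyTreatment()], [runGrid()]
#' @export
canonicalTreatments <- function()
  c("raw", "snv", "msc", "mf5", "mf9", "mf11", "sg1", "sg2")

#' Apply a named pre-treatment to a train/test pair
#'
#' Dispatches a treatment tag to the corresponding transform. Treatments
#' are per-spectrum except MSC, whose reference is fitted on the training
#' split and applied frozen to the test split.
#'
#' @param train,test [SpectralDataset-class] splits (test may be `NULL`).
#' @param treatment one of [canonicalTreatments()].
#' @param sg_window,sg_polyorder_1,sg_polyorder_2 Savitzky-Golay controls.
#' @return list with transformed `train` and `test`.
#' @export
applyTreatment <- function(train, test = NULL, treatment = "raw",
                           sg_window = 11L, sg_polyorder_1 = 2L,
                           sg_polyorder_2 = 3L) {
  f <- switch(treatment,
    raw = identity,
    snv = snv,
    msc = {
      ref <- mscFit(train)
      function(x) mscApply(x, ref)
    },
    mf5 = function(x) meanFilter(x, 5L),
    mf9 = function(x) meanFilter(x, 9L),
    mf11 = function(x) meanFilter(x, 11L),
    sg1 = function(x) savgolDerivative(x, 1L, sg_window, sg_polyorder_1),
    sg2 = function(x) savgolDerivative(x, 2L, sg_window, sg_polyorder_2),
    stop("unknown treatment '", treatment, "'"))
  list(train = f(train), test = if (is.null(test)) NULL else f(test))
}
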