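#' HyperCube: a hyperspectral datacube
#'
#' A three-dimensional image cube (rows x cols x bands) with a wavelength
#' axis, as produced by a line-scan Vis-NIR camera. The canonical in-memory
#' layout is band-last, row-major in the spatial plane; interleave only
#' matters on disk (see [readENVI()]). The `scale` slot records whether the
#' values are raw digital numbers or calibrated reflectance.
#'
#' @slot data numeric array, rows x cols x bands.
#' @slot wavelengths numeric vector of band-centre wavelengths in nm,
#'   strictly increasing, length equal to the band axis.
#' @slot scale `"digital_number"` or `"reflectance"`.
#' @slot header named list of ENVI header fields carried through I/O
#'   (unknown keys are preserved on rewrite) plus diagnostics such as the
#'   degenerate-denominator pixel count after calibration.
#'
#' @seealso [readENVI()], [writeENVI()], [calibrate()], [cropROI()],
#'   [meanSpectrum()]
#' @export
setClass("HyperCube",
  representation(
    data = "array",
    wavelengths = "numeric",
    scale = "character",
    header = "list"
  ),
  prototype(scale = "digital_number", header = list())
)

setValidity("HyperCube", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3L)
    msg <- c(msg, "data must be a rows x cols x bands array")
  else if (length(object@wavelengths) != d[3L])
    msg <- c(msg, sprintf("wavelengths length (%d) != band count (%d)",
                          length(object@wavelengths), d[3L]))
  if (length(object@wavelengths) > 1L &&
      any(diff(object@wavelengths) <= 0))
    msg <- c(msg, "wavelengths must be strictly increasing")
  if (!object@scale %in% c("digital_number", "reflectance"))
    msg <- c(msg, "scale must be 'digital_number' or 'reflectance'")
  if (object@scale == "reflectance" && any(is.infinite(object@data)))
    msg <- c(msg, "reflectance cube contains non-finite values")
  if (length(msg)) msg else TRUE
})

#' Construct a HyperCube
#'
#' @param data numeric array, rows x cols x bands. A matrix is promoted to a
#'   single-band cube.
#' @param wavelengths band-centre wavelengths in nm.
#' @param scale `"digital_number"` (default) or `"reflectance"`.
#' @param header optional named list of header metadata.
#' @return A [HyperCube-class] object.
#' @examples
#' cube <- HyperCube(array(runif(4 * 4 * 6), c(4, 4, 6)),
#'                   wavelengths = seq(400, 900, length.out = 6),
#'                   scale = "reflectance")
#' dim(cube)
#' @export
HyperCube <- function(data, wavelengths, scale = "digital_number",
                      header = list()) {
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  new("HyperCube", data = data, wavelengths = as.numeric(wavelengths),
      scale = scale, header = header)
}

#' @describeIn HyperCube spatial and spectral dimensions
#'   (rows, cols, bands).
#' @param x a `HyperCube`
#' @export
setMethod("dim", "HyperCube", function(x) dim(x@data))

setMethod("show", "HyperCube", function(object) {
  d <- dim(object@data)
  cat(sprintf("HyperCube: %d x %d pixels, %d bands (%.1f-%.1f nm), %s\n",
              d[1], d[2], d[3], min(object@wavelengths),
              max(object@wavelengths), object@scale))
  if (object@scale == "reflectance") {
    out <- sum(object@data < 0 | object@data > 1.2, na.rm = TRUE)
    if (out > 0)
      cat(sprintf("  note: %d pixel values outside [0, 1.2]\n", out))
    nas <- sum(is.na(object@data))
    if (nas > 0)
      cat(sprintf("  note: %d missing (degenerate-calibration) values\n", nas))
  }
})

#' Spectrum: a single reflectance (or derivative) spectrum
#'
#' One spectrum on a wavelength axis, typically the ROI mean of a calibrated
#' cube.
#'
#' @slot wavelengths nm vector.
#' @slot values numeric vector, same length.
#' @export
setClass("Spectrum",
  representation(wavelengths = "numeric", values = "numeric"))

setValidity("Spectrum", function(object) {
  if (length(object@wavelengths) != length(object@values))
    return("wavelengths and values differ in length")
  if (any(!is.finite(object@values)))
    return("values must be finite")
  TRUE
})

#' @rdname Spectrum-class
#' @param wavelengths nm vector.
#' @param values numeric vector.
#' @export
Spectrum <- function(wavelengths, values)
  new("Spectrum", wavelengths = as.numeric(wavelengths),
      values = as.numeric(values))

setMethod("show", "Spectrum", function(object) {
  cat(sprintf("Spectrum: %d bands (%.1f-%.1f nm), values in [%.4g, %.4g]\n",
              length(object@values), min(object@wavelengths),
              max(object@wavelengths), min(object@values),
              max(object@values)))
})

#' SpectralDataset: sample spectra with reference chemistry
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding the
#' sample-by-band data the regression models consume: the `"spectra"` assay
#' is bands x samples, `rowData()$wavelength` is the wavelength axis in nm,
#' and `colData()` carries per-sample reference chemistry (`gingerol`,
#' `shogaol` in mg/g and their unitless `ratio`, the modelled response).
#' `metadata()$treatment` records the pre-treatment provenance tag.
#'
#' Use [spectraMatrix()] for the samples x bands matrix, [wavelengths()] for
#' the axis and [ratios()] for the response.
#'
#' @export
setClass("SpectralDataset", contains = "SummarizedExperiment")

setValidity("SpectralDataset", function(object) {
  msg <- character()
  if (!"spectra" %in% assayNames(object))
    msg <- c(msg, "assay 'spectra' is required")
  wl <- rowData(object)$wavelength
  if (is.null(wl))
    msg <- c(msg, "rowData must carry a 'wavelength' column (nm)")
  else if (length(wl) > 1L && any(diff(wl) <= 0))
    msg <- c(msg, "wavelength axis must be strictly increasing")
  if (!"ratio" %in% colnames(colData(object)))
    msg <- c(msg, "colData must carry a 'ratio' column")
  if (length(msg)) msg else TRUE
})

#' Construct a SpectralDataset
#'
#' @param spectra samples x bands numeric matrix (one row per sample).
#' @param wavelengths nm vector, length `ncol(spectra)`.
#' @param reference data.frame with one row per sample; must contain
#'   `ratio`, typically also `gingerol` and `shogaol` (mg/g). Row order
#'   matches `spectra`.
#' @param treatment pre-treatment provenance tag (default `"raw"`).
#' @return A [SpectralDataset-class].
#' @export
SpectralDataset <- function(spectra, wavelengths, reference,
                            treatment = "raw") {
  spectra <- as.matrix(spectra)
  stopifnot(ncol(spectra) == length(wavelengths),
            nrow(spectra) == nrow(reference))
  if (is.null(rownames(spectra)))
    rownames(spectra) <- if (!is.null(reference$sample_id))
      as.character(reference$sample_id) else paste0("S", seq_len(nrow(spectra)))
  se <- SummarizedExperiment(
    assays = list(spectra = t(spectra)),
    rowData = DataFrame(wavelength = as.numeric(wavelengths)),
    colData = DataFrame(reference, row.names = rownames(spectra))
  )
  out <- new("SpectralDataset", se)
  metadata(out)$treatment <- treatment
  out
}

#' SplitSpec: a reproducible train/test partition
#'
#' @slot test_fraction proportion of samples held out (default 0.2).
#' @slot seed integer RNG seed for the permutation (default 20).
#' @slot train_indices,test_indices disjoint, exhaustive 1-based index sets;
#'   `length(test_indices) == round(test_fraction * N)`.
#' @seealso [splitDataset()]
#' @export
setClass("SplitSpec",
  representation(test_fraction = "numeric", seed = "numeric",
                 train_indices = "integer", test_indices = "integer"))

setValidity("SplitSpec", function(object) {
  n <- length(object@train_indices) + length(object@test_indices)
  if (length(intersect(object@train_indices, object@test_indices)))
    return("train and test indices overlap")
  if (n > 0 && !setequal(c(object@train_indices, object@test_indices),
                         seq_len(n)))
    return("train and test indices must partition 1..N")
  if (object@test_fraction <= 0 || object@test_fraction >= 1)
    return("test_fraction must lie in (0, 1)")
  TRUE
})

setMethod("show", "SplitSpec", function(object) {
  cat(sprintf("SplitSpec: %d train / %d test (fraction %.2f, seed %d)\n",
              length(object@train_indices), length(object@test_indices),
              object@test_fraction, as.integer(object@seed)))
})

#' PLSRModel: a NIPALS partial least squares regression fit
#'
#' Single-response PLS1 decomposition X = T P' + E, y = T q' + f on
#' mean-centred data, with the regression vector assembled as
#' beta = W (P'W)^-1 q. Scores are mutually orthogonal; prediction through
#' beta equals prediction through the score pathway.
#'
#' @slot n_lvs number of latent variables J.
#' @slot weights K x J weight matrix W, unit-norm columns.
#' @slot scores N x J score matrix T.
#' @slot x_loadings K x J loading matrix P.
#' @slot y_loadings length-J response loadings q.
#' @slot coefficients length-K regression vector beta (centred scale).
#' @slot x_mean,y_mean centring constants.
#' @slot residuals_x,residuals_y deflation residuals E and f.
#' @slot fitted training-set fitted values (original y scale).
#' @slot rmsecv leave-one-out RMSE per candidate J (empty unless selected
#'   via [selectNumLVs()]).
#' @slot wavelengths nm axis of the predictor bands (provenance).
#' @seealso [fitPLSR()], [selectNumLVs()], [vipScores()], [betaSelect()]
#' @export
setClass("PLSRModel",
  representation(n_lvs = "integer", weights = "matrix", scores = "matrix",
                 x_loadings = "matrix", y_loadings = "numeric",
                 coefficients = "numeric", x_mean = "numeric",
                 y_mean = "numeric", residuals_x = "matrix",
                 residuals_y = "numeric", fitted = "numeric",
                 rmsecv = "numeric", wavelengths = "numeric"))

setMethod("show", "PLSRModel", function(object) {
  cat(sprintf("PLSRModel: %d latent variable(s), %d bands\n",
              object@n_lvs, length(object@coefficients)))
  if (length(object@rmsecv))
    cat(sprintf("  RMSECV at J*: %.4g\n", min(object@rmsecv)))
})

#' @describeIn PLSRModel regression coefficients on the centred scale.
#' @param object a fitted model
#' @param ... unused
#' @export
setMethod("coef", "PLSRModel", function(object, ...) object@coefficients)

#' LassoModel: an L1-penalised least-squares fit
#'
#' Minimises the residual sum of squares plus `alpha` times the L1 norm of
#' the coefficients (no 1/(2N) scaling), on mean-centred predictors and
#' response, by cyclic coordinate descent with soft thresholding. For
#' objectives scaled by 1/(2N) (e.g. glmnet), the equivalent penalty is
#' `lambda = alpha / (2 * N)`.
#'
#' @slot alpha the regularisation strength used for the fit.
#' @slot coefficients length-K coefficient vector (centred scale).
#' @slot intercept intercept on the original scale.
#' @slot x_mean,y_mean centring constants.
#' @slot active_set indices of non-zero coefficients.
#' @slot alpha_grid,cv_rmse penalty grid and leave-one-out RMSE per value
#'   (empty unless selected via [selectAlpha()]).
#' @slot n_iter coordinate-descent sweeps used.
#' @slot wavelengths nm axis of the predictor bands (provenance).
#' @seealso [fitLasso()], [selectAlpha()]
#' @export
setClass("LassoModel",
  representation(alpha = "numeric", coefficients = "numeric",
                 intercept = "numeric", x_mean = "numeric",
                 y_mean = "numeric", active_set = "integer",
                 alpha_grid = "numeric", cv_rmse = "numeric",
                 n_iter = "integer", wavelengths = "numeric"))

setMethod("show", "LassoModel", function(object) {
  cat(sprintf("LassoModel: alpha = %.4g, %d of %d coefficients active\n",
              object@alpha, length(object@active_set),
              length(object@coefficients)))
})

#' @describeIn LassoModel coefficients on the centred predictor scale.
#' @param object a fitted model
#' @param ... unused
#' @export
setMethod("coef", "LassoModel", function(object, ...) object@coefficients)

#' SelectionResult: retained wavelengths after variable selection
#'
#' @slot method `"beta_coefficient"` or `"vip"`.
#' @slot scores per-band score (absolute beta coefficient, or VIP).
#' @slot threshold retention cutoff in score units; bands with
#'   score >= threshold are kept.
#' @slot retained_indices 1-based band indices retained.
#' @slot retained_wavelengths nm values of the retained bands.
#' @slot n_bands total band count before selection.
#' @seealso [betaSelect()], [vipSelect()], [refitOnSelection()]
#' @export
setClass("SelectionResult",
  representation(method = "character", scores = "numeric",
                 threshold = "numeric", retained_indices = "integer",
                 retained_wavelengths = "numeric", n_bands = "integer"))

setValidity("SelectionResult", function(object) {
  k <- length(object@retained_indices)
  if (k < 1L || k > object@n_bands)
    return("retained set must be non-empty and within the band count")
  if (length(object@retained_wavelengths) != k)
    return("retained wavelengths length mismatch")
  TRUE
})

setMethod("show", "SelectionResult", function(object) {
  cat(sprintf("SelectionResult (%s): %d of %d bands retained (threshold %.4g)\n",
              object@method, length(object@retained_indices),
              object@n_bands, object@threshold))
})

#' EvaluationReport: one row of the model-grid table
#'
#' Training/testing R-squared, RMSE and RPD, limit of detection, a quality
#' flag (`"good"` when the testing RPD is at least 1.4, else `"poor"`) and
#' model provenance.
#'
#' @slot r2_train,r2_test coefficient of determination per split.
#' @slot rmse_train,rmse_test root mean square error (ratio units).
#' @slot rpd_train,rpd_test ratio of performance to deviation.
#' @slot lod limit of detection, 3 x calibration RMSE / calibration slope
#'   (ratio units).
#' @slot quality `"good"` or `"poor"`.
#' @slot treatment,model_type,selection provenance tags.
#' @slot hyperparameter the chosen J (PLSR) or alpha (LASSO).
#' @slot n_bands predictor bands used by the fit.
#' @seealso [evaluateModel()], [runGrid()]
#' @export
setClass("EvaluationReport",
  representation(r2_train = "numeric", r2_test = "numeric",
                 rmse_train = "numeric", rmse_test = "numeric",
                 rpd_train = "numeric", rpd_test = "numeric",
                 lod = "numeric", quality = "character",
                 treatment = "character", model_type = "character",
                 hyperparameter = "numeric", selection = "character",
                 n_bands = "integer"))

setValidity("EvaluationReport", function(object) {
  if (object@rmse_train < 0 || object@rmse_test < 0)
    return("RMSE must be non-negative")
  ok <- if (object@rpd_test >= 1.4) "good" else "poor"
  if (object@quality != ok)
    return("quality flag inconsistent with testing RPD")
  TRUE
})

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf(
    "EvaluationReport [%s / %s%s]\n  R2  train %.3f  test %.3f\n  RMSE train %.3f  test %.3f\n  RPD train %.2f  test %.2f   LOD %.2f  (%s)\n",
    object@treatment, object@model_type,
    if (object@selection == "none") "" else paste0(" / ", object@selection),
    object@r2_train, object@r2_test, object@rmse_train, object@rmse_test,
    object@rpd_train, object@rpd_test, object@lod, object@quality))
})

#' @describeIn EvaluationReport flatten to a one-row data.frame (the shape
#'   used by the grid table).
#' @param x an `EvaluationReport`
#' @param row.names,optional,... passed over from the generic, unused
#' @export
as.data.frame.EvaluationReport <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  data.frame(treatment = x@treatment, model = x@model_type,
             selection = x@selection, hyperparameter = x@hyperparameter,
             n_bands = x@n_bands,
             r2_train = x@r2_train, r2_test = x@r2_test,
             rmse_train = x@rmse_train, rmse_test = x@rmse_test,
             rpd_train = x@rpd_train, rpd_test = x@rpd_test,
             lod = x@lod, quality = x@quality,
             stringsAsFactors = FALSE)
}

#' GridResult: the full pre-treatment x model grid
#'
#' @slot results data.frame, one row per fitted model cell (32 in the
#'   canonical configuration), in canonical treatment order.
#' @slot models named list of the fitted model objects per cell.
#' @slot split the shared [SplitSpec-class].
#' @slot manifest run metadata: seeds, config hash, package/R versions.
#' @seealso [runGrid()], [bestModels()]
#' @export
setClass("GridResult",
  representation(results = "data.frame", models = "list",
                 split = "SplitSpec", manifest = "list"))

setMethod("show", "GridResult", function(object) {
  cat(sprintf("GridResult: %d model cells (%d failed)\n",
              nrow(object@results), sum(!is.na(object@results$error) &
                                        object@results$error != "")))
  cat("  families:",
      paste(unique(paste(object@results$model, object@results$selection,
                         sep = "/")), collapse = ", "), "\n")
})
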