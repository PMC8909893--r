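#' @rdname wavelengths
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' Wavelength axis accessor
#'
#' Returns the band-centre wavelengths (nm) of a cube, spectrum, dataset or
#' fitted model.
#'
#' @param x a [HyperCube-class], [Spectrum-class], [SpectralDataset-class],
#'   [PLSRModel-class] or [LassoModel-class].
#' @return numeric vector of wavelengths in nm.
#' @rdname wavelengths
#' @export
setMethod("wavelengths", "HyperCube", function(x) x@wavelengths)

#' @rdname wavelengths
#' @export
setMethod("wavelengths", "Spectrum", function(x) x@wavelengths)

#' @rdname wavelengths
#' @export
setMethod("wavelengths", "SpectralDataset",
          function(x) rowData(x)$wavelength)

#' @rdname wavelengths
#' @export
setMethod("wavelengths", "PLSRModel", function(x) x@wavelengths)

#' @rdname wavelengths
#' @export
setMethod("wavelengths", "LassoModel", function(x) x@wavelengths)

#' Spectra matrix accessor
#'
#' The samples x bands predictor matrix X of a [SpectralDataset-class]
#' (transpose of the internal bands x samples assay).
#'
#' @param x a `SpectralDataset`.
#' @return numeric matrix, one row per sample.
#' @export
setGeneric("spectraMatrix", function(x) standardGeneric("spectraMatrix"))

#' @rdname spectraMatrix
#' @export
setMethod("spectraMatrix", "SpectralDataset", function(x) t(assay(x, "spectra")))

#' Response accessor: gingerol-to-shogaol ratios
#'
#' @param x a [SpectralDataset-class].
#' @return numeric vector, one unitless ratio per sample.
#' @export
setGeneric("ratios", function(x) standardGeneric("ratios"))

#' @rdname ratios
#' @export
setMethod("ratios", "SpectralDataset", function(x) colData(x)$ratio)

#' Pre-treatment provenance tag
#'
#' @param x a [SpectralDataset-class].
#' @return character tag, e.g. `"raw"`, `"snv"`, `"sg2"`.
#' @export
setGeneric("treatmentTag", function(x) standardGeneric("treatmentTag"))

#' @rdname treatmentTag
#' @export
setMethod("treatmentTag", "SpectralDataset",
          function(x) metadata(x)$treatment %||% "raw")
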