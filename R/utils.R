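`%||%` <- function(a, b) if (is.null(a)) b else a

## population (1/n) standard deviation
sdPop <- function(x) sqrt(mean((x - mean(x))^2))

## uniform band spacing in nm; errors if the axis is not uniform
bandSpacing <- function(wavelengths, tol = 1e-6) {
  d <- diff(wavelengths)
  if (length(d) == 0L) stop("need at least two bands")
  if (max(d) - min(d) > tol * mean(d))
    stop("wavelength axis is not uniformly spaced")
  mean(d)
}

## md5 of an R object via its serialisation (manifest config hash)
objectHash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

stopIfNotMatrix <- function(X) {
  X <- as.matrix(X)
  if (!is.numeric(X)) stop("X must be a numeric matrix")
  X
}
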