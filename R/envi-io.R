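## ENVI .hdr/.dat reader-writer. Only the uncompressed, untiled dialect is
## supported: data types 4 (float32) and 5 (float64), interleaves BSQ, BIL
## and BIP, little-endian byte order. Unknown header keys are carried in
## HyperCube@header and written back verbatim.

.enviKnownKeys <- c("samples", "lines", "bands", "header offset",
                    "file type", "data type", "interleave", "byte order",
                    "wavelength units", "wavelength")

parseEnviHeader <- function(header_path) {
  lines <- readLines(header_path, warn = FALSE)
  if (!length(lines) || !grepl("^ENVI", lines[[1]]))
    stop("not an ENVI header: ", header_path)
  txt <- paste(lines[-1], collapse = "\n")
  out <- list()
  pos <- 1L
  ## key = value, where value is either a { ... } block (may span lines)
  ## or the remainder of the line
  pat <- "(?m)^\\s*([^=\\n]+?)\\s*=\\s*"
  ml <- gregexpr(pat, txt, perl = TRUE)
  m <- ml[[1]]
  if (m[1] == -1) return(out)
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  keys <- regmatches(txt, ml)[[1]]
  keys <- sub("\\s*=\\s*$", "", sub("^\\s*", "", keys))
  for (i in seq_along(starts)) {
    vstart <- starts[i] + lens[i]
    rest <- substr(txt, vstart, nchar(txt))
    if (grepl("^\\{", rest)) {
      close <- regexpr("\\}", rest)
      if (close == -1) stop("unterminated { } block for key '", keys[i], "'")
      val <- substr(rest, 2, close - 1)
      val <- gsub("\\s+", " ", trimws(val))
    } else {
      val <- sub("\n.*$", "", rest)
      val <- trimws(val)
    }
    out[[tolower(keys[i])]] <- val
  }
  out
}

.enviDataFile <- function(header_path) {
  base <- sub("\\.hdr$", "", header_path, ignore.case = TRUE)
  for (cand in c(paste0(base, ".dat"), paste0(base, ".raw"),
                 paste0(base, ".img"), base))
    if (file.exists(cand) && !dir.exists(cand)) return(cand)
  stop("no data file found for header ", header_path)
}

#' Read an ENVI hyperspectral cube
#'
#' Reads a paired ENVI header/data file into a [HyperCube-class] in the
#' package's canonical band-last layout, whatever interleave (BSQ, BIL or
#' BIP) the file declares. The `wavelength` header list (nm) is required.
#' Data types 4 (32-bit float) and 5 (64-bit float) are supported.
#'
#' @param header_path path to the `.hdr` file. The data file is looked up as
#'   the same basename with extension `.dat`, `.raw`, `.img` or none.
#' @param scale value scale of the cube, `"digital_number"` (default) or
#'   `"reflectance"`.
#' @return A [HyperCube-class]; unknown header keys are preserved in its
#'   `header` slot.
#' @seealso [writeENVI()]
#' @export
readENVI <- function(header_path, scale = "digital_number") {
  hdr <- parseEnviHeader(header_path)
  for (k in c("samples", "lines", "bands"))
    if (is.null(hdr[[k]])) stop("ENVI header missing key '", k, "'")
  cols <- as.integer(hdr[["samples"]])
  rows <- as.integer(hdr[["lines"]])
  bands <- as.integer(hdr[["bands"]])
  dtype <- as.integer(hdr[["data type"]] %||% 4L)
  if (!dtype %in% c(4L, 5L))
    stop("unsupported ENVI data type ", dtype, " (only 4 and 5)")
  interleave <- tolower(hdr[["interleave"]] %||% "bsq")
  if (!interleave %in% c("bsq", "bil", "bip"))
    stop("unsupported interleave '", interleave, "'")
  if (is.null(hdr[["wavelength"]]))
    stop("ENVI header missing key 'wavelength'")
  wl <- as.numeric(strsplit(hdr[["wavelength"]], ",")[[1]])
  if (length(wl) != bands)
    stop(sprintf("wavelength list length (%d) != bands (%d)",
                 length(wl), bands))
  data_file <- .enviDataFile(header_path)
  size <- if (dtype == 4L) 4L else 8L
  n <- rows * cols * bands
  offset <- as.integer(hdr[["header offset"]] %||% 0L)
  expected <- offset + as.numeric(n) * size
  actual <- file.info(data_file)$size
  if (!isTRUE(all.equal(expected, actual)))
    stop(sprintf(
      "ENVI dimension mismatch: header declares %d x %d x %d (%s bytes) but %s has %s bytes",
      rows, cols, bands, format(expected), basename(data_file),
      format(actual)))
  con <- file(data_file, "rb")
  on.exit(close(con))
  if (offset > 0) readBin(con, "raw", offset)
  v <- readBin(con, "double", n = n, size = size, endian = "little")
  arr <- switch(interleave,
    bsq = aperm(array(v, c(cols, rows, bands)), c(2, 1, 3)),
    bil = aperm(array(v, c(cols, bands, rows)), c(3, 1, 2)),
    bip = aperm(array(v, c(bands, cols, rows)), c(3, 2, 1)))
  extra <- hdr[setdiff(names(hdr), .enviKnownKeys)]
  HyperCube(arr, wl, scale = scale, header = extra)
}

#' Write a HyperCube as an ENVI .hdr/.dat pair
#'
#' Writes little-endian binary data in the requested interleave plus a text
#' header carrying dimensions, data type, interleave and the wavelength list
#' in nm. Any non-standard keys in `cube@header` are appended to the header,
#' so a read-modify-write cycle preserves them.
#'
#' @param cube a [HyperCube-class].
#' @param path output basename or `.hdr` path; `<path>.hdr` and
#'   `<path>.dat` are produced.
#' @param interleave `"bil"` (default), `"bsq"` or `"bip"`.
#' @param data_type ENVI data type code: 4 for 32-bit float (default) or 5
#'   for 64-bit float. Round-trips are bit-exact for the declared type.
#' @return Invisibly, a character vector of the two file paths.
#' @seealso [readENVI()]
#' @export
writeENVI <- function(cube, path, interleave = "bil", data_type = 4L) {
  stopifnot(is(cube, "HyperCube"))
  interleave <- tolower(interleave)
  if (!interleave %in% c("bsq", "bil", "bip"))
    stop("unsupported interleave '", interleave, "'")
  if (!data_type %in% c(4L, 5L))
    stop("unsupported ENVI data type ", data_type, " (only 4 and 5)")
  base <- sub("\\.(hdr|dat)$", "", path, ignore.case = TRUE)
  hdr_path <- paste0(base, ".hdr")
  dat_path <- paste0(base, ".dat")
  d <- dim(cube@data)
  v <- switch(interleave,
    bsq = as.vector(aperm(cube@data, c(2, 1, 3))),
    bil = as.vector(aperm(cube@data, c(2, 3, 1))),
    bip = as.vector(aperm(cube@data, c(3, 2, 1))))
  con <- file(dat_path, "wb")
  writeBin(v, con, size = if (data_type == 4L) 4L else 8L,
           endian = "little")
  close(con)
  wl <- paste(format(cube@wavelengths, trim = TRUE, digits = 10),
              collapse = ", ")
  lines <- c(
    "ENVI",
    paste0("samples = ", d[2]),
    paste0("lines = ", d[1]),
    paste0("bands = ", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    paste0("data type = ", data_type),
    paste0("interleave = ", interleave),
    "byte order = 0",
    "wavelength units = Nanometers",
    paste0("wavelength = { ", wl, " }"))
  extra <- cube@header[setdiff(names(cube@header), .enviKnownKeys)]
  extra <- extra[vapply(extra, function(x)
    is.character(x) || is.numeric(x), logical(1))]
  for (k in names(extra))
    lines <- c(lines, paste0(k, " = ", paste(extra[[k]], collapse = ", ")))
  writeLines(lines, hdr_path)
  invisible(c(hdr = hdr_path, dat = dat_path))
}
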