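#' @include utils.R
NULL

# Minimal NPY (v1.0) support for 2D arrays: enough to exchange depth and IR
# frames with numeric tooling. Little-endian float32/float64/int32/uint16.

npyMagic <- as.raw(c(0x93, charToRaw("NUMPY")))

#' Write a matrix as an NPY file
#'
#' @param m numeric or integer matrix.
#' @param path output path.
#' @param dtype `"f8"` (default), `"f4"`, or `"i4"`.
#' @return `path`, invisibly.
#' @export
writeNpy <- function(m, path, dtype = c("f8", "f4", "i4")) {
  dtype <- match.arg(dtype)
  stopifnot(is.matrix(m))
  header <- sprintf("{'descr': '<%s', 'fortran_order': False, 'shape': (%d, %d), }",
                    dtype, nrow(m), ncol(m))
  total <- 10L + nchar(header) + 1L
  pad <- (64L - total %% 64L) %% 64L
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(npyMagic, con)
  writeBin(as.raw(c(1L, 0L)), con)
  writeBin(as.integer(nchar(header)), con, size = 2L, endian = "little")
  writeChar(header, con, eos = NULL)
  v <- as.numeric(t(m))  # C order
  if (dtype == "f8") writeBin(v, con, size = 8L, endian = "little")
  else if (dtype == "f4") writeBin(v, con, size = 4L, endian = "little")
  else writeBin(as.integer(v), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read an NPY file into a matrix
#'
#' @param path NPY file (v1.x, 2D, little-endian numeric).
#' @return A matrix.
#' @export
readNpy <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6L)
  if (!identical(magic, npyMagic)) stopf("corrupt file: '%s' is not NPY", path)
  ver <- readBin(con, "raw", 2L)
  hlen <- readBin(con, "integer", 1L, size = 2L, endian = "little", signed = FALSE)
  header <- readChar(con, hlen, useBytes = TRUE)
  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", header)
  fortran <- grepl("'fortran_order':\\s*True", header)
  shapeStr <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", header)
  shape <- as.integer(strsplit(gsub("\\s", "", shapeStr), ",")[[1]])
  if (length(shape) == 1L) shape <- c(shape, 1L)
  if (length(shape) != 2L) stopf("only 2D NPY arrays are supported")
  n <- prod(shape)
  v <- switch(descr,
    "<f8" = readBin(con, "double", n, size = 8L, endian = "little"),
    "<f4" = readBin(con, "double", n, size = 4L, endian = "little"),
    "<i4" = as.numeric(readBin(con, "integer", n, size = 4L, endian = "little")),
    "<u2" = as.numeric(readBin(con, "integer", n, size = 2L, endian = "little",
                               signed = FALSE)),
    stopf("unsupported NPY dtype '%s'", descr))
  if (length(v) < n) stopf("corrupt file: '%s' is truncated", path)
  if (fortran) matrix(v, shape[1], shape[2])
  else t(matrix(v, shape[2], shape[1]))
}
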