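#' @include AllClasses.R
NULL

#' Write a point cloud or mesh to PLY
#'
#' ASCII or binary little-endian PLY with float64 vertex coordinates (so
#' round trips are bit exact) and, when present, triangle faces.
#'
#' @param x a [PointCloud-class] or [MRSurface-class].
#' @param path output path.
#' @param format `"binary"` (little-endian, default) or `"ascii"`.
#' @return `path`, invisibly.
#' @export
writePly <- function(x, path, format = c("binary", "ascii")) {
  format <- match.arg(format)
  pts <- if (is(x, "MRSurface")) x@vertices else x@points
  tri <- if (is(x, "MRSurface")) x@triangles else matrix(integer(0), 0, 3)
  fmt <- if (format == "binary") "binary_little_endian" else "ascii"
  header <- c("ply", sprintf("format %s 1.0", fmt),
              sprintf("element vertex %d", nrow(pts)),
              "property double x", "property double y", "property double z")
  if (nrow(tri) > 0)
    header <- c(header, sprintf("element face %d", nrow(tri)),
                "property list uchar int vertex_indices")
  header <- c(header, "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  if (format == "ascii") {
    writeLines(apply(pts, 1, function(r) paste(sprintf("%.17g", r), collapse = " ")), con)
    if (nrow(tri) > 0)
      writeLines(apply(tri, 1, function(r) paste(c(3L, r - 1L), collapse = " ")), con)
  } else {
    writeBin(as.numeric(t(pts)), con, size = 8L, endian = "little")
    for (i in seq_len(nrow(tri))) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(tri[i, ] - 1L), con, size = 4L, endian = "little")
    }
  }
  invisible(path)
}

#' Read a PLY file
#'
#' Supports ASCII and binary little-endian PLY with float/double vertex
#' coordinates and optional triangular faces; extra vertex properties are
#' skipped.
#'
#' @param path PLY file.
#' @param frame frame label for a point-only file.
#' @return An [MRSurface-class] when faces are present, else a
#'   [PointCloud-class].
#' @export
readPly <- function(path, frame = "unknown") {
  con <- file(path, "rb")
  on.exit(close(con))
  line <- function() {
    out <- raw(0)
    repeat {
      b <- readBin(con, "raw", 1L)
      if (length(b) == 0L) stopf("corrupt file: unexpected end of header in '%s'", path)
      if (b == as.raw(10L)) break
      out <- c(out, b)
    }
    sub("\r$", "", rawToChar(out))
  }
  if (!identical(line(), "ply")) stopf("corrupt file: '%s' is not PLY", path)
  fmt <- NULL; nv <- 0L; nf <- 0L
  vprops <- character(0); inVertex <- FALSE; inFace <- FALSE
  repeat {
    l <- line()
    if (grepl("^format", l)) fmt <- strsplit(l, "\\s+")[[1]][2]
    else if (grepl("^element vertex", l)) {
      nv <- as.integer(strsplit(l, "\\s+")[[1]][3]); inVertex <- TRUE; inFace <- FALSE
    } else if (grepl("^element face", l)) {
      nf <- as.integer(strsplit(l, "\\s+")[[1]][3]); inVertex <- FALSE; inFace <- TRUE
    } else if (grepl("^element", l)) { inVertex <- FALSE; inFace <- FALSE }
    else if (grepl("^property", l) && inVertex) {
      vprops <- c(vprops, paste(strsplit(l, "\\s+")[[1]][-1], collapse = " "))
    } else if (identical(l, "end_header")) break
  }
  if (is.null(fmt)) stopf("corrupt file: no format line in '%s'", path)
  ptypes <- vapply(strsplit(vprops, " "), `[`, "", 1L)
  pnames <- vapply(strsplit(vprops, " "), function(x) x[length(x)], "")
  sizes <- c(float = 4L, float32 = 4L, double = 8L, float64 = 8L,
             uchar = 1L, uint8 = 1L, char = 1L, int8 = 1L,
             short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
             int = 4L, int32 = 4L, uint = 4L, uint32 = 4L)
  xyzCols <- match(c("x", "y", "z"), pnames)
  if (any(is.na(xyzCols))) stopf("PLY file lacks x/y/z vertex properties")
  if (fmt == "ascii") {
    txt <- readLines(con, n = nv + nf)
    if (length(txt) < nv + nf) stopf("corrupt file: '%s' is truncated", path)
    vm <- do.call(rbind, lapply(txt[seq_len(nv)], function(l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
    pts <- vm[, xyzCols, drop = FALSE]
    tri <- if (nf > 0) do.call(rbind, lapply(txt[nv + seq_len(nf)], function(l) {
      v <- as.integer(strsplit(trimws(l), "\\s+")[[1]])
      if (v[1] != 3L) stopf("only triangular faces are supported")
      v[2:4] + 1L
    })) else matrix(integer(0), 0, 3)
  } else if (fmt == "binary_little_endian") {
    pts <- matrix(0, nv, 3)
    readProp <- function(type) {
      s <- sizes[[type]]
      if (type %in% c("float", "float32")) readBin(con, "double", 1L, size = 4L, endian = "little")
      else if (type %in% c("double", "float64")) readBin(con, "double", 1L, size = 8L, endian = "little")
      else if (s == 1L) as.numeric(readBin(con, "integer", 1L, size = 1L, signed = FALSE))
      else readBin(con, "integer", 1L, size = s, endian = "little")
    }
    for (i in seq_len(nv)) {
      vals <- vapply(ptypes, readProp, numeric(1))
      if (length(vals) < 3L) stopf("corrupt file: '%s' is truncated", path)
      pts[i, ] <- vals[xyzCols]
    }
    tri <- matrix(integer(0), 0, 3)
    if (nf > 0) {
      tri <- matrix(0L, nf, 3)
      for (i in seq_len(nf)) {
        cnt <- readBin(con, "integer", 1L, size = 1L, signed = FALSE)
        if (length(cnt) == 0L) stopf("corrupt file: '%s' is truncated", path)
        if (cnt != 3L) stopf("only triangular faces are supported")
        idx <- readBin(con, "integer", 3L, size = 4L, endian = "little")
        if (length(idx) < 3L) stopf("corrupt file: '%s' is truncated", path)
        tri[i, ] <- idx + 1L
      }
    }
  } else stopf("unsupported PLY format '%s'", fmt)
  if (nrow(pts) == 0L) stopf("corrupt file: '%s' has no vertices", path)
  if (nf > 0) mrSurface(pts, tri, provenance = "mesh-file")
  else pointCloud(pts, frame = frame)
}
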