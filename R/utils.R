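#' @useDynLib SurfNav, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods new validObject is slot
#' @importFrom stats lm coef vcov rnorm runif sd median quantile setNames
#' @importFrom utils head tail read.csv write.csv
NULL

# Run `expr` under a fixed RNG state without disturbing the caller's stream.
withLocalSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed and an index, staying inside 32-bit range.
childSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k) * 9973) %% 2147483399) + 1L
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

frameError <- function(what, want, got) {
  stopf("frame mismatch in %s: expected '%s', got '%s'", what, want, got)
}

asPointMatrix <- function(x, arg = "points") {
  x <- as.matrix(x)
  if (ncol(x) != 3L) stopf("'%s' must be an N x 3 matrix", arg)
  storage.mode(x) <- "double"
  if (!all(is.finite(x))) stopf("'%s' contains non-finite coordinates", arg)
  x
}

asPixelMatrix <- function(x, arg = "pixels") {
  if (is.null(dim(x))) x <- matrix(x, ncol = 2L, byrow = TRUE)
  x <- as.matrix(x)
  if (ncol(x) != 2L) stopf("'%s' must be an N x 2 matrix of (u, v)", arg)
  storage.mode(x) <- "double"
  x
}
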