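#' @include geometry.R
NULL

# Hartley normalisation: translate centroid to origin, scale mean distance
# to sqrt(2). Returns the 3x3 conditioning matrix.
hartleyMatrix <- function(pts) {
  ctr <- colMeans(pts)
  d <- sqrt(rowSums(sweep(pts, 2, ctr)^2))
  s <- if (mean(d) > 1e-12) sqrt(2) / mean(d) else 1
  matrix(c(s, 0, -s * ctr[1], 0, s, -s * ctr[2], 0, 0, 1), 3, 3, byrow = TRUE)
}

homographyResiduals <- function(par, src, dst) {
  H <- matrix(c(par, 1), 3, 3, byrow = TRUE)
  P <- cbind(src, 1) %*% t(H)
  as.numeric(P[, 1:2] / P[, 3] - dst)
}

#' Estimate a homography between two pixel sets
#'
#' Normalised direct linear transform (Hartley preconditioning) with optional
#' Levenberg-Marquardt refinement of the symmetric-free transfer error.
#' Input pixels are assumed already undistorted. The returned matrix is
#' canonicalised with `H[3,3] = 1` and the fit carries the reprojection RMSE
#' (root-mean-square Euclidean distance between `H src` and `dst`).
#'
#' @param src,dst N x 2 matrices of corresponding pixels (N >= 4).
#' @param refine run LM refinement after the DLT (default TRUE).
#' @param sourceCamera,targetCamera camera labels stored on the result.
#' @return A [HomographyFit-class].
#' @export
estimateHomography <- function(src, dst, refine = TRUE,
                               sourceCamera = "IR", targetCamera = "RGB") {
  src <- asPixelMatrix(src, "src"); dst <- asPixelMatrix(dst, "dst")
  n <- nrow(src)
  if (n < 4L) stopf("homography estimation needs at least 4 point pairs, got %d", n)
  if (nrow(dst) != n) stopf("src and dst must have the same number of rows")
  Ts <- hartleyMatrix(src); Td <- hartleyMatrix(dst)
  sn <- cbind(src, 1) %*% t(Ts); dn <- cbind(dst, 1) %*% t(Td)
  A <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    x <- sn[i, ]; u <- dn[i, 1]; v <- dn[i, 2]
    A[2 * i - 1, ] <- c(x, 0, 0, 0, -u * x)
    A[2 * i, ]     <- c(0, 0, 0, x, -v * x)
  }
  sv <- svd(A, nu = 0, nv = 9)
  if (sv$d[8] < 1e-12 * sv$d[1])
    stopf("degenerate configuration: design matrix is rank-deficient")
  Hn <- matrix(sv$v[, 9], 3, 3, byrow = TRUE)
  H <- solve(Td) %*% Hn %*% Ts
  if (abs(H[3, 3]) < 1e-12) stopf("degenerate homography (H[3,3] ~ 0)")
  H <- H / H[3, 3]
  if (refine) {
    fit <- minpack.lm::nls.lm(as.numeric(t(H))[1:8], fn = homographyResiduals,
                              src = src, dst = dst,
                              control = minpack.lm::nls.lm.control(maxiter = 100,
                                                                   ftol = 1e-15, ptol = 1e-15))
    Hr <- matrix(c(fit$par, 1), 3, 3, byrow = TRUE)
    # keep the refined matrix only if it did not worsen the residual
    if (sum(homographyResiduals(fit$par, src, dst)^2) <=
        sum(homographyResiduals(as.numeric(t(H))[1:8], src, dst)^2)) H <- Hr
  }
  h <- homography(H, sourceCamera, targetCamera)
  res <- applyHomography(h, src) - dst
  new("HomographyFit", homography = h, rmse = sqrt(mean(rowSums(res^2))),
      nPoints = as.integer(n))
}

#' Estimate an inter-camera homography from a corner table
#'
#' Pools the corner correspondences of every shot shared by the two cameras
#' (matched by shot/row/col) and fits one homography, as the rig calibration
#' does at the common interpolated resolution.
#'
#' @param corners data frame with columns `camera, shot, row, col, u, v`.
#' @param pair string `"SRC:DST"`, e.g. `"IR:RGB"`.
#' @param refine run LM refinement (default TRUE).
#' @return A [HomographyFit-class].
#' @export
calibrateHomographyFromCorners <- function(corners, pair, refine = TRUE) {
  cams <- strsplit(pair, ":")[[1]]
  if (length(cams) != 2L) stopf("pair must be of the form 'SRC:DST'")
  a <- corners[corners$camera == cams[1], ]
  b <- corners[corners$camera == cams[2], ]
  key <- function(d) paste(d$shot, d$row, d$col)
  common <- intersect(key(a), key(b))
  if (length(common) < 4L)
    stopf("fewer than 4 shared corners between %s and %s", cams[1], cams[2])
  a <- a[match(common, key(a)), ]; b <- b[match(common, key(b)), ]
  estimateHomography(cbind(a$u, a$v), cbind(b$u, b$v), refine = refine,
                     sourceCamera = cams[1], targetCamera = cams[2])
}

#' Rescale chessboard corners between image resolutions
#'
#' Corner coordinates measured at one resolution are mapped to another by the
#' per-axis scale factors `target / native`.
#'
#' @param grid a [CornerGrid-class].
#' @param nativeSize `(width, height)` the corners were measured at.
#' @param targetSize `(width, height)` to scale to.
#' @return A [CornerGrid-class] with scaled corners.
#' @export
upscaleCorners <- function(grid, nativeSize, targetSize) {
  if (any(nativeSize <= 0) || any(targetSize <= 0)) stopf("sizes must be positive")
  sx <- targetSize[1] / nativeSize[1]; sy <- targetSize[2] / nativeSize[2]
  cornerGrid(cbind(grid@corners[, 1] * sx, grid@corners[, 2] * sy),
             grid@gridRows, grid@gridCols, grid@camera)
}

#' Warp an image through a fitted homography
#'
#' Inverse-warp resampling: each target pixel is mapped back through `H^-1`
#' and bilinearly interpolated in the source image. Pixels falling outside the
#' source are `NA`.
#'
#' @param image numeric matrix `[height, width]` (single channel).
#' @param fit a [HomographyFit-class] or [Homography-class] mapping source
#'   pixels to target pixels.
#' @param targetCamera a [CameraModel-class] giving the output size (or a
#'   `c(width, height)` pair).
#' @return Warped matrix `[targetHeight, targetWidth]` with `NA` outside.
#' @export
overlayImage <- function(image, fit, targetCamera) {
  h <- if (is(fit, "HomographyFit")) fit@homography else fit
  size <- if (is(targetCamera, "CameraModel")) c(targetCamera@width, targetCamera@height)
          else as.integer(targetCamera)
  w <- size[1]; ht <- size[2]
  Hinv <- solve(h@H)
  uv <- cbind(rep(0:(w - 1), each = ht), rep(0:(ht - 1), times = w))
  suv <- applyHomography(Hinv, uv)
  sx <- suv[, 1]; sy <- suv[, 2]
  # snap coordinates a rounding error outside the source onto its border
  eps <- 1e-6
  sx[sx > -eps & sx < 0] <- 0
  sy[sy > -eps & sy < 0] <- 0
  sx[sx > ncol(image) - 1 & sx < ncol(image) - 1 + eps] <- ncol(image) - 1
  sy[sy > nrow(image) - 1 & sy < nrow(image) - 1 + eps] <- nrow(image) - 1
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  hS <- nrow(image); wS <- ncol(image)
  valid <- x0 >= 0 & y0 >= 0 & x0 <= wS - 2 & y0 <= hS - 2
  # allow exact right/bottom border
  edgeX <- x0 == wS - 1 & abs(fx) < 1e-9
  edgeY <- y0 == hS - 1 & abs(fy) < 1e-9
  valid <- valid | (x0 >= 0 & y0 >= 0 &
                    (x0 <= wS - 2 | edgeX) & (y0 <= hS - 2 | edgeY))
  out <- rep(NA_real_, w * ht)
  if (any(valid)) {
    x0v <- pmin(x0[valid], wS - 2); y0v <- pmin(y0[valid], hS - 2)
    fxv <- sx[valid] - x0v; fyv <- sy[valid] - y0v
    i00 <- cbind(y0v + 1, x0v + 1)
    v00 <- image[i00]
    v10 <- image[cbind(y0v + 1, x0v + 2)]
    v01 <- image[cbind(y0v + 2, x0v + 1)]
    v11 <- image[cbind(y0v + 2, x0v + 2)]
    out[valid] <- (1 - fxv) * (1 - fyv) * v00 + fxv * (1 - fyv) * v10 +
                  (1 - fxv) * fyv * v01 + fxv * fyv * v11
  }
  matrix(out, nrow = ht, ncol = w, byrow = FALSE)
}
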