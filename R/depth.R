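#' @include geometry.R
NULL

# Evaluate a polynomial with ascending coefficients at x.
polyEval <- function(coefficients, x) {
  y <- rep(0, length(x))
  for (k in rev(seq_along(coefficients))) y <- y * x + coefficients[k]
  y
}

#' Fit a polynomial depth-bias correction
#'
#' Fits corrected (true) depth as a polynomial in raw sensor depth by least
#' squares, following the plane-sweep protocol: the camera-to-plane distance
#' measured by the tracker is compared against the sensor's reported depth at
#' a series of stations. The fit is performed on a centred basis for
#' conditioning and expanded back to raw-depth coefficients. Monotonicity of
#' the corrected depth over the fitted range is enforced.
#'
#' @param measurements two-column matrix or data frame `(trueDistance, rawDepth)`
#'   in mm; at least `degree + 1` distinct raw depths.
#' @param degree polynomial degree (default 2).
#' @return A [DepthCorrection-class] with coefficients (ascending order, raw
#'   depth basis), their standard errors, the fitted range and residual RMSE.
#' @export
fitDepthCorrection <- function(measurements, degree = 2L) {
  m <- as.matrix(measurements)[, 1:2, drop = FALSE]
  true <- m[, 1]; raw <- m[, 2]
  if (length(unique(round(raw, 9))) < max(3L, degree + 1L))
    stopf("need at least %d distinct raw depths", max(3L, degree + 1L))
  ctr <- mean(raw)
  X <- outer(raw - ctr, 0:degree, `^`)
  fit <- lm.fit(X, true)
  # expand centred coefficients a_k (x - c)^k to raw basis
  a <- fit$coefficients
  coefRaw <- rep(0, degree + 1)
  for (k in 0:degree) {
    for (j in 0:k) {
      coefRaw[j + 1] <- coefRaw[j + 1] + a[k + 1] * choose(k, j) * (-ctr)^(k - j)
    }
  }
  res <- fit$residuals
  dof <- length(true) - (degree + 1)
  sigma2 <- if (dof > 0) sum(res^2) / dof else 0
  XtXinv <- chol2inv(chol(crossprod(X)))
  # propagate to raw-basis coefficients through the (linear) basis change
  Bmat <- matrix(0, degree + 1, degree + 1)
  for (k in 0:degree) for (j in 0:k) Bmat[j + 1, k + 1] <- choose(k, j) * (-ctr)^(k - j)
  covRaw <- Bmat %*% (XtXinv * sigma2) %*% t(Bmat)
  seRaw <- sqrt(pmax(diag(covRaw), 0))
  rng <- range(raw)
  corr <- new("DepthCorrection", coefficients = coefRaw, fitRange = rng,
              residualRmse = sqrt(mean(res^2)), stdErrors = seRaw)
  # monotonicity of the corrected value over the fitted range
  grid <- seq(rng[1], rng[2], length.out = 200)
  if (any(diff(polyEval(coefRaw, grid)) <= 0))
    stopf(paste("fitted correction is not monotone increasing over [%g, %g] mm;",
                "refit with a lower polynomial degree"), rng[1], rng[2])
  corr
}

#' Apply a depth correction to a frame
#'
#' Each valid (> 0) pixel is replaced by the polynomial value; invalid pixels
#' stay 0. Depths outside the fitted range are corrected anyway but counted.
#'
#' @param frame a [DepthFrame-class].
#' @param correction a [DepthCorrection-class].
#' @return The corrected [DepthFrame-class], with attribute
#'   `"nOutOfRange"` giving the number of extrapolated pixels.
#' @export
applyDepthCorrection <- function(frame, correction) {
  d <- frame@depth
  valid <- d > 0
  nOut <- sum(valid & (d < correction@fitRange[1] | d > correction@fitRange[2]))
  d[valid] <- polyEval(correction@coefficients, d[valid])
  d[valid & d < 0] <- 0   # a pathological correction cannot create negative depth
  out <- depthFrame(d, frame@camera, frame@timestamp)
  attr(out, "nOutOfRange") <- nOut
  out
}

#' Map a face bounding box from RGB to depth (IR) pixel coordinates
#'
#' The four corners of the box are pushed through the RGB-to-IR homography;
#' the output is the axis-aligned hull of the mapped corners, clamped to the
#' depth image bounds.
#'
#' @param roi a [FaceROI-class] in RGB pixels.
#' @param h an RGB-to-IR [Homography-class] (an IR-to-RGB one is inverted
#'   automatically if its labels say so).
#' @param irCamera the IR [CameraModel-class] (for clamping).
#' @return A [FaceROI-class] in IR/depth pixel coordinates.
#' @export
projectRoiToDepth <- function(roi, h, irCamera) {
  if (identical(h@sourceCamera, "IR") && !identical(h@targetCamera, "IR"))
    h <- invertHomography(h)
  b <- roi@bbox
  corners <- rbind(c(b[1], b[2]), c(b[3], b[2]), c(b[3], b[4]), c(b[1], b[4]))
  mapped <- applyHomography(h, corners)
  u <- range(mapped[, 1]); v <- range(mapped[, 2])
  w <- irCamera@width; ht <- irCamera@height
  u <- pmin(pmax(u, 0), w - 1); v <- pmin(pmax(v, 0), ht - 1)
  if (u[1] >= u[2] || v[1] >= v[2])
    stopf("empty ROI: face bounding box maps entirely outside the depth image")
  faceROI(c(u[1], v[1], u[2], v[2]), source = roi@source)
}

#' Extract the face point cloud from a depth frame
#'
#' Applies the depth correction, keeps the valid pixels inside the region of
#' interest, and unprojects them with the IR camera intrinsics into the IR
#' optical frame.
#'
#' @param frame a [DepthFrame-class] (raw depths).
#' @param roi a [FaceROI-class] in IR/depth pixel coordinates.
#' @param correction a [DepthCorrection-class]; identity by default.
#' @param minPoints minimum number of valid pixels (default 100) below which
#'   registration would be meaningless and an error is raised.
#' @return A [PointCloud-class] in frame `"optical"`.
#' @export
extractFaceCloud <- function(frame, roi, correction = identityDepthCorrection(),
                             minPoints = 100L) {
  corrected <- applyDepthCorrection(frame, correction)
  d <- corrected@depth
  b <- roi@bbox
  cols <- max(0, ceiling(b[1])):min(ncol(d) - 1, floor(b[3]))
  rows <- max(0, ceiling(b[2])):min(nrow(d) - 1, floor(b[4]))
  sub <- d[rows + 1, cols + 1, drop = FALSE]
  valid <- which(sub > 0, arr.ind = TRUE)
  if (nrow(valid) < minPoints)
    stopf("insufficient surface: only %d valid depth pixels inside the ROI (need >= %d)",
          nrow(valid), minPoints)
  u <- cols[valid[, 2]]; v <- rows[valid[, 1]]
  z <- sub[valid]
  pts <- unprojectPixels(frame@camera, cbind(u, v), z)
  pointCloud(pts, frame = "optical")
}

#' Voxel-downsample a point cloud
#'
#' Averages points falling in the same cubic voxel; order-independent.
#'
#' @param cloud a [PointCloud-class] (or N x 3 matrix).
#' @param voxel voxel edge length, mm.
#' @param method `"centroid"` averages the points of each voxel (smooths
#'   noise but moves points off a curved surface); `"sample"` keeps the first
#'   point of each voxel (stays exactly on the measured surface).
#' @return Same type as the input, downsampled.
#' @export
voxelDownsample <- function(cloud, voxel = 5, method = c("centroid", "sample")) {
  method <- match.arg(method)
  pts <- if (is(cloud, "PointCloud")) cloud@points else asPointMatrix(cloud)
  key <- paste(floor(pts[, 1] / voxel), floor(pts[, 2] / voxel), floor(pts[, 3] / voxel))
  if (method == "sample") {
    out <- pts[!duplicated(key), , drop = FALSE]
  } else {
    grp <- match(key, unique(key))
    out <- cbind(tapply(pts[, 1], grp, mean), tapply(pts[, 2], grp, mean),
                 tapply(pts[, 3], grp, mean))
    dimnames(out) <- NULL
  }
  if (is(cloud, "PointCloud")) pointCloud(out, cloud@frame) else out
}
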