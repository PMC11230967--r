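#' @include geometry.R
NULL

#' Detect saturated reflective markers in an IR image
#'
#' Retro-reflective markers saturate the infrared sensor, so detection is a
#' threshold at (a fraction of) the saturation level followed by connected
#' component labelling. Each component's centroid is computed with intensity
#' weighting for sub-pixel accuracy. Components smaller than `minArea` pixels
#' are discarded; components whose area is a strong outlier (more than
#' `mergedAreaFactor` times the median blob area) are flagged as suspected
#' merges of overlapping markers.
#'
#' @param image numeric matrix `[height, width]` with intensities in `[0, 1]`
#'   (1 = saturation).
#' @param saturationThreshold intensity threshold; default 0.98 of the dynamic
#'   range.
#' @param minArea minimum component area in pixels (default 3).
#' @param mergedAreaFactor area-outlier factor for the merged-blob flag.
#' @param refineMargin half-width (px) of the window around each saturated
#'   component over which the sub-pixel centroid is refined using the full
#'   (sub-threshold) intensity profile; 0 restricts the centroid to the
#'   saturated pixels themselves.
#' @return A [MarkerObservation-class]; zero rows when nothing saturates.
#' @export
detectMarkers <- function(image, saturationThreshold = 0.98, minArea = 3L,
                          mergedAreaFactor = 1.4, refineMargin = 12L) {
  if (length(image) == 0L) stopf("empty image")
  if (saturationThreshold < 0 || saturationThreshold > 1)
    stopf("saturationThreshold must lie in [0, 1]")
  mask <- image >= saturationThreshold
  empty <- new("MarkerObservation",
               centroids = matrix(numeric(0), 0, 2),
               pixelCounts = integer(0), mergedSuspect = logical(0))
  if (!any(mask)) return(empty)
  lab <- EBImage::bwlabel(mask)
  labv <- as.integer(lab)
  keep <- which(labv > 0L)
  counts <- tabulate(labv[keep])
  ids <- which(counts >= minArea)
  if (length(ids) == 0L) return(empty)
  h <- nrow(image); wI <- ncol(image)
  cent <- matrix(0, length(ids), 2)
  pc <- integer(length(ids))
  for (k in seq_along(ids)) {
    px <- which(labv == ids[k])
    row0 <- (px - 1L) %% h          # 0-based row  -> v
    col0 <- (px - 1L) %/% h         # 0-based col  -> u
    if (refineMargin > 0L) {
      r0 <- max(min(row0) - refineMargin, 0L); r1 <- min(max(row0) + refineMargin, h - 1L)
      c0 <- max(min(col0) - refineMargin, 0L); c1 <- min(max(col0) + refineMargin, wI - 1L)
      win <- image[(r0:r1) + 1L, (c0:c1) + 1L, drop = FALSE]
      wgt <- pmax(win - min(win), 0)
      s <- sum(wgt)
      cent[k, ] <- c(c0 + sum(rep(0:(c1 - c0), each = nrow(win)) * wgt) / s,
                     r0 + sum(rep(0:(r1 - r0), times = ncol(win)) * wgt) / s)
    } else {
      w <- image[px]
      cent[k, ] <- c(sum(col0 * w), sum(row0 * w)) / sum(w)
    }
    pc[k] <- length(px)
  }
  merged <- if (length(ids) >= 3L) pc > mergedAreaFactor * median(pc)
            else rep(FALSE, length(ids))
  new("MarkerObservation", centroids = cent, pixelCounts = pc, mergedSuspect = merged)
}

#' Pair tool markers with image centroids by the linear-tool ordering rule
#'
#' The calibration tool carries collinear markers; correspondences are formed
#' by sorting the 3D markers by descending tracker-world x and the detected
#' centroids by ascending image u, then zipping: the marker with the highest
#' x corresponds to the centroid with the lowest u.
#'
#' @param observation a [MarkerObservation-class].
#' @param toolMarkerPositions N x 3 matrix of marker centres in tracker world (mm).
#' @param collinearityTol maximum RMS off-axis deviation (mm) allowed for the
#'   tool markers (they must form a line).
#' @param tieTol minimum separation (mm in x, px in u) below which ordering is
#'   ambiguous and an error is raised.
#' @return List of `X` (N x 3 world points) and `pixels` (N x 2 centroids),
#'   row-aligned.
#' @export
orderCorrespondences <- function(observation, toolMarkerPositions,
                                 collinearityTol = 2, tieTol = 1e-6) {
  X <- asPointMatrix(toolMarkerPositions, "toolMarkerPositions")
  U <- observation@centroids
  if (nrow(U) != nrow(X))
    stopf("correspondence error: %d centroids but %d tool markers", nrow(U), nrow(X))
  n <- nrow(X)
  if (n >= 3L) {
    ctr <- sweep(X, 2, colMeans(X))
    sv <- svd(ctr, nu = 0, nv = 0)$d
    if (sqrt(mean(sv[-1]^2) / n) > collinearityTol)
      stopf("tool markers are not collinear within %g mm", collinearityTol)
  }
  if (n > 1L) {
    if (min(diff(sort(X[, 1]))) < tieTol)
      stopf("ambiguous ordering: tool marker x-coordinates tie within %g", tieTol)
    if (min(diff(sort(U[, 1]))) < tieTol)
      stopf("ambiguous ordering: centroid u-coordinates tie within %g", tieTol)
  }
  ox <- order(X[, 1], decreasing = TRUE)
  ou <- order(U[, 1], decreasing = FALSE)
  list(X = X[ox, , drop = FALSE], pixels = U[ou, , drop = FALSE])
}

# Is a 3D point set collinear (used to detect PnP degeneracy)?
isCollinear <- function(X, tol = 1e-6) {
  if (nrow(X) < 3L) return(TRUE)
  sv <- svd(sweep(X, 2, colMeans(X)), nu = 0, nv = 0)$d
  sv[2] < tol * max(sv[1], 1)
}

# Residuals (pixels, interleaved u then v) of projecting world points under
# pose (rotation vector, translation): optical <- world.
pnpResiduals <- function(par, X, pixels, camera) {
  R <- rotationVectorToMatrix(par[1:3])
  P <- sweep(X %*% t(R), 2L, -par[4:6], "-")
  if (any(P[, 3] <= 1e-9)) return(rep(1e6, 2 * nrow(X)))
  uv <- projectPoints(camera, P)
  as.numeric(uv - pixels)
}

#' Estimate a camera pose from 3D-2D correspondences (PnP)
#'
#' Direct linear transform initialisation (for six or more well-spread
#' points) followed by Levenberg-Marquardt refinement of the reprojection
#' error; pixels are undistorted internally with the camera's rational model.
#' For fewer than six points the refinement is started from a set of coarse
#' initial orientations and the best reprojection wins.
#'
#' @param X N x 3 matrix of points in the world frame (mm).
#' @param pixels N x 2 matrix of observed `(u, v)`.
#' @param camera a [CameraModel-class].
#' @param worldFrame,opticalFrame frame labels for the result.
#' @return A [RigidTransform-class] `V` (world frame <- optical frame): the
#'   pose of the optical frame in the world.
#' @export
solvePnp <- function(X, pixels, camera, worldFrame = "tracker", opticalFrame = "optical") {
  X <- asPointMatrix(X, "X"); pixels <- asPixelMatrix(pixels)
  n <- nrow(X)
  if (n < 4L) stopf("PnP needs at least 4 correspondences, got %d", n)
  if (nrow(pixels) != n) stopf("X and pixels must have the same number of rows")
  if (isCollinear(X, 1e-8))
    stopf(paste("rank deficiency: all 3D points are collinear; a single view of a",
                "linear tool cannot fix the pose - pool captures with the tool",
                "re-oriented before solving"))
  K <- camera@K
  xyd <- cbind((pixels[, 1] - K[1, 3]) / K[1, 1], (pixels[, 2] - K[2, 3]) / K[2, 2])
  xy <- undistortNormalized(camera, xyd)

  inits <- list()
  if (n >= 6L) {
    # DLT on normalized coordinates
    A <- matrix(0, 2 * n, 12)
    for (i in seq_len(n)) {
      Xi <- c(X[i, ], 1)
      A[2 * i - 1, ] <- c(Xi, rep(0, 4), -xy[i, 1] * Xi)
      A[2 * i, ]     <- c(rep(0, 4), Xi, -xy[i, 2] * Xi)
    }
    sv <- svd(A)
    P <- matrix(sv$v[, 12], 3, 4, byrow = TRUE)
    Rraw <- P[, 1:3]
    # positive-depth sign
    if (mean(cbind(X, 1) %*% P[3, ]) < 0) { P <- -P; Rraw <- -Rraw }
    s <- svd(Rraw)
    if (s$d[3] > 1e-8 * s$d[1]) {
      R0 <- s$u %*% t(s$v)
      if (det(R0) < 0) R0 <- s$u %*% diag(c(1, 1, -1)) %*% t(s$v)
      t0 <- P[, 4] / mean(s$d)
      inits[[length(inits) + 1]] <- c(rotationMatrixToVector(R0), t0)
    }
  }
  if (length(inits) == 0L) {
    # coarse multi-start: centre the points in front of the camera at the
    # distance suggested by the image spread, for a set of viewing rotations
    ctr <- colMeans(X)
    span3d <- max(apply(X, 2, function(v) diff(range(v))))
    span2d <- max(apply(xy, 2, function(v) diff(range(v))))
    dist0 <- if (span2d > 1e-9) span3d / span2d else 500
    axes <- rbind(c(0,0,0), c(pi,0,0), c(0,pi,0), c(0,0,pi),
                  c(pi/2,0,0), c(-pi/2,0,0), c(0,pi/2,0), c(0,-pi/2,0),
                  c(pi/2,pi/2,0), c(-pi/2,pi/2,0), c(pi/2,0,pi/2), c(0,pi/2,pi/2))
    for (i in seq_len(nrow(axes))) {
      R0 <- rotationVectorToMatrix(axes[i, ])
      t0 <- c(0, 0, dist0) - R0 %*% ctr
      inits[[length(inits) + 1]] <- c(axes[i, ], t0)
    }
  }
  best <- NULL; bestSS <- Inf
  for (par0 in inits) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par0, fn = pnpResiduals, X = X, pixels = pixels,
                         camera = camera,
                         control = minpack.lm::nls.lm.control(maxiter = 200,
                                                              ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ss <- sum(fit$fvec^2)
    if (ss < bestSS) { bestSS <- ss; best <- fit$par }
  }
  if (is.null(best)) stopf("PnP optimisation failed for all initialisations")
  R <- rotationVectorToMatrix(best[1:3]); t <- best[4:6]
  # pose solved is optical <- world; V is the optical frame's pose in world
  invert(rigidTransform(R, t, frameFrom = worldFrame, frameTo = opticalFrame))
}

#' Body-to-optical calibration from one pose pair
#'
#' Given the tracked camera-body pose `C` (world <- body) and the camera pose
#' `V` (world <- optical) estimated by PnP, the fixed transform is
#' `M = C^-1 V` (body <- optical).
#'
#' @param C [RigidTransform-class], tracker world <- camera body.
#' @param V [RigidTransform-class], tracker world <- optical frame.
#' @return `M` as a [RigidTransform-class].
#' @export
calibrationFromPoses <- function(C, V) compose(invert(C), V)

# Extract ordered (X, pixels) correspondences from a capture.
captureCorrespondences <- function(capture, saturationThreshold = 0.98, ...) {
  obs <- detectMarkers(capture@irImage, saturationThreshold, ...)
  orderCorrespondences(obs, capture@toolMarkerPositions)
}

#' Calibrate the tracked-body-to-optical-centre transform M
#'
#' From IR images of a tracked linear marker tool, estimates the fixed
#' transform `M` between the rigid body attached to the camera group and the
#' IR camera's optical centre. Markers are detected by saturation, paired by
#' the linear-tool ordering rule, and the pose is solved by PnP.
#'
#' Two estimation strategies are available. `"pooled"` (default) maps every
#' marker through its capture's `C^-1` into the camera-body frame, where the
#' constant pose `M^-1` is a single PnP problem over all captures jointly;
#' this remains well-posed for a collinear tool as long as the tool is
#' re-oriented between captures. `"per-capture"` solves one PnP per capture
#' (each capture must then be individually well-posed, i.e. non-collinear
#' markers), forms `M_i = C_i^-1 V_i`, checks their consistency, and averages
#' them (chordal quaternion mean + translation mean).
#'
#' @param captures list of [CalibrationCapture-class].
#' @param camera the IR [CameraModel-class].
#' @param saturationThreshold marker detection threshold (fraction of range).
#' @param method `"pooled"` or `"per-capture"`.
#' @param rotationSpreadTol maximum allowed angular spread (degrees) of the
#'   per-capture estimates before a calibration-inconsistency error.
#' @param bodyFrame,opticalFrame,worldFrame frame labels.
#' @return A [TrackingCalibration-class] with per-capture reprojection RMSE
#'   computed using the final `M`.
#' @export
calibrateTracking <- function(captures, camera, saturationThreshold = 0.98,
                              method = c("pooled", "per-capture"),
                              rotationSpreadTol = 5,
                              bodyFrame = "body", opticalFrame = "optical",
                              worldFrame = "tracker") {
  method <- match.arg(method)
  if (length(captures) < 1L) stopf("need at least one capture")
  corr <- lapply(captures, captureCorrespondences, saturationThreshold = saturationThreshold)

  if (method == "pooled") {
    Yall <- NULL; pall <- NULL
    for (i in seq_along(captures)) {
      Ci <- captures[[i]]@cameraBodyPose
      Y <- transformPoints(invert(Ci), corr[[i]]$X)
      Yall <- rbind(Yall, Y); pall <- rbind(pall, corr[[i]]$pixels)
    }
    if (isCollinear(Yall, 1e-6))
      stopf(paste("rank deficiency: pooled body-frame markers are still collinear;",
                  "re-orient the tool between captures or use a non-collinear tool"))
    # with body-frame points, the "camera pose in the world" solved by PnP is
    # exactly the optical frame's pose in the body frame, i.e. M
    M <- solvePnp(Yall, pall, camera,
                  worldFrame = bodyFrame, opticalFrame = opticalFrame)
  } else {
    Ms <- vector("list", length(captures))
    for (i in seq_along(captures)) {
      if (isCollinear(corr[[i]]$X, 1e-6))
        stopf(paste("capture %d has collinear markers; per-capture PnP is degenerate -",
                    "use method = 'pooled'"), i)
      Vi <- solvePnp(corr[[i]]$X, corr[[i]]$pixels, camera,
                     worldFrame = worldFrame, opticalFrame = opticalFrame)
      Ci <- captures[[i]]@cameraBodyPose
      Ms[[i]] <- calibrationFromPoses(Ci, Vi)
    }
    M <- averageTransforms(Ms)
    ang <- vapply(Ms, function(Mi) rotationAngleBetween(Mi, M) * 180 / pi, numeric(1))
    if (max(ang) > rotationSpreadTol)
      stopf("calibration inconsistency: capture(s) %s deviate > %g deg from the mean M",
            paste(which(ang > rotationSpreadTol), collapse = ", "), rotationSpreadTol)
  }

  calib <- new("TrackingCalibration", M = M, rmsePerCapture = numeric(0),
               nCaptures = length(captures))
  calib@rmsePerCapture <- vapply(seq_along(captures), function(i)
    reprojectionRmse(calib, captures[i], camera,
                     saturationThreshold = saturationThreshold), numeric(1))
  calib
}

#' Reprojection RMSE of a tracking calibration
#'
#' Projects every tool marker of every capture through the calibrated chain
#' `(C M)^-1` (world to optical) and compares with the detected centroids.
#'
#' @param calibration a [TrackingCalibration-class].
#' @param captures list of [CalibrationCapture-class].
#' @param camera the IR [CameraModel-class].
#' @param saturationThreshold detection threshold.
#' @return Root-mean-square pixel distance pooled over all markers.
#' @export
reprojectionRmse <- function(calibration, captures, camera, saturationThreshold = 0.98) {
  Mm <- transformMatrix(calibration@M)
  d2 <- numeric(0)
  for (cap in captures) {
    corr <- captureCorrespondences(cap, saturationThreshold)
    CM <- transformMatrix(cap@cameraBodyPose) %*% Mm    # world <- optical
    Winv <- solve(CM)
    Xopt <- sweep(corr$X %*% t(Winv[1:3, 1:3]), 2L, -Winv[1:3, 4], "-")
    uv <- projectPoints(camera, Xopt)
    d2 <- c(d2, rowSums((uv - corr$pixels)^2))
  }
  sqrt(mean(d2))
}
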