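#' @include AllGenerics.R
NULL

#' @rdname compose
setMethod("compose", signature("RigidTransform", "RigidTransform"), function(A, B) {
  if (!identical(A@frameFrom, B@frameTo))
    frameError("compose", A@frameFrom, B@frameTo)
  rigidTransform(A@matrix %*% B@matrix, frameFrom = B@frameFrom, frameTo = A@frameTo)
})

#' @rdname compose
#' @export
setMethod("%*%", signature("RigidTransform", "RigidTransform"), function(x, y) compose(x, y))

#' @rdname invert
setMethod("invert", "RigidTransform", function(A) {
  R <- A@matrix[1:3, 1:3]; t <- A@matrix[1:3, 4]
  rigidTransform(t(R), -crossprod(R, t), frameFrom = A@frameTo, frameTo = A@frameFrom)
})

#' @rdname transformPoints
setMethod("transformPoints", signature("RigidTransform", "matrix"), function(A, x) {
  x <- asPointMatrix(x, "x")
  R <- A@matrix[1:3, 1:3]; t <- A@matrix[1:3, 4]
  sweep(x %*% t(R), 2L, -t, "-")
})

#' @rdname transformPoints
setMethod("transformPoints", signature("RigidTransform", "PointCloud"), function(A, x) {
  if (!identical(x@frame, A@frameFrom)) frameError("transformPoints", A@frameFrom, x@frame)
  pointCloud(transformPoints(A, x@points), frame = A@frameTo)
})

# ---- rotation parameterisations -------------------------------------------

#' Rotation conversions
#'
#' Conversions between 3x3 rotation matrices, unit quaternions `(w, x, y, z)`
#' and rotation vectors (axis times angle, radians).
#'
#' @param R rotation matrix.
#' @param q unit quaternion `(w, x, y, z)`.
#' @param v rotation vector (rad).
#' @return The requested representation.
#' @name rotations
NULL

#' @rdname rotations
#' @export
rotationToQuaternion <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s, (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s, (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s, (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  q / sqrt(sum(q^2))
}

#' @rdname rotations
#' @export
quaternionToRotation <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)), 3, 3, byrow = TRUE)
}

#' @rdname rotations
#' @export
rotationVectorToMatrix <- function(v) {
  th <- sqrt(sum(v^2))
  if (th < 1e-12) return(diag(3) + skewMatrix(v))
  k <- v / th
  K <- skewMatrix(k)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' @rdname rotations
#' @export
rotationMatrixToVector <- function(R) {
  q <- rotationToQuaternion(R)
  if (q[1] < 0) q <- -q
  s <- sqrt(sum(q[2:4]^2))
  if (s < 1e-12) return(c(0, 0, 0))
  2 * atan2(s, q[1]) * q[2:4] / s
}

skewMatrix <- function(v)
  matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3, byrow = TRUE)

quaternionMultiply <- function(a, b) {
  c(a[1] * b[1] - sum(a[2:4] * b[2:4]),
    a[1] * b[2:4] + b[1] * a[2:4] + c(a[3] * b[4] - a[4] * b[3],
                                      a[4] * b[2] - a[2] * b[4],
                                      a[2] * b[3] - a[3] * b[2]))
}

quaternionConjugate <- function(q) c(q[1], -q[2:4])

#' Angle of the relative rotation between two transforms
#'
#' @param A,B [RigidTransform-class] objects (frame labels ignored).
#' @return Angle in radians of `R_A %*% t(R_B)`.
#' @export
rotationAngleBetween <- function(A, B) {
  RA <- transformMatrix(A)[1:3, 1:3]; RB <- transformMatrix(B)[1:3, 1:3]
  sqrt(sum(rotationMatrixToVector(RA %*% t(RB))^2))
}

#' Translation distance between two transforms
#' @param A,B [RigidTransform-class] objects.
#' @return Euclidean distance between translations, mm.
#' @export
translationDistance <- function(A, B)
  sqrt(sum((transformMatrix(A)[1:3, 4] - transformMatrix(B)[1:3, 4])^2))

# Chordal L2 mean of unit quaternions: principal eigenvector of sum(q q^T).
quaternionMean <- function(Q) {
  Q <- as.matrix(Q)
  ref <- Q[1, ]
  for (i in seq_len(nrow(Q))) if (sum(Q[i, ] * ref) < 0) Q[i, ] <- -Q[i, ]
  A <- crossprod(Q)
  e <- eigen(A, symmetric = TRUE)
  q <- e$vectors[, 1]
  if (q[1] < 0) q <- -q
  q / sqrt(sum(q^2))
}

#' Average a list of rigid transforms
#'
#' Geodesic-style mean: chordal quaternion mean for the rotation and the
#' arithmetic mean of translations. Frame labels are taken from the first
#' element; all elements must share them.
#'
#' @param transforms list of [RigidTransform-class].
#' @return A [RigidTransform-class].
#' @export
averageTransforms <- function(transforms) {
  stopifnot(length(transforms) >= 1L)
  f0 <- frameFrom(transforms[[1]]); t0 <- frameTo(transforms[[1]])
  Q <- t(vapply(transforms, function(A) rotationToQuaternion(transformMatrix(A)[1:3, 1:3]),
                numeric(4)))
  tr <- t(vapply(transforms, function(A) transformMatrix(A)[1:3, 4], numeric(3)))
  rigidTransform(quaternionToRotation(quaternionMean(Q)), colMeans(tr), f0, t0)
}

# ---- rational distortion model --------------------------------------------

# Forward distortion on normalized coordinates (N x 2 matrix).
distortNormalized <- function(camera, xy) {
  d <- unname(camera@distortion)  # k1..k6, p1, p2
  x <- xy[, 1]; y <- xy[, 2]
  r2 <- x^2 + y^2
  radial <- (1 + d[1] * r2 + d[2] * r2^2 + d[3] * r2^3) /
            (1 + d[4] * r2 + d[5] * r2^2 + d[6] * r2^3)
  xd <- x * radial + 2 * d[7] * x * y + d[8] * (r2 + 2 * x^2)
  yd <- y * radial + d[7] * (r2 + 2 * y^2) + 2 * d[8] * x * y
  cbind(xd, yd, deparse.level = 0)
}

# Inverse distortion by damped fixed-point iteration.
undistortNormalized <- function(camera, xyd, maxIter = 50L, tol = 1e-8) {
  if (all(camera@distortion == 0)) return(xyd)
  xy <- xyd
  for (i in seq_len(maxIter)) {
    f <- distortNormalized(camera, xy)
    err <- xyd - f
    if (max(abs(err)) < tol) return(xy)
    xy <- xy + 0.9 * err   # damping keeps strong distortion stable
  }
  if (max(abs(xyd - distortNormalized(camera, xy))) > 1e-4)
    stopf("undistortion did not converge within %d iterations", maxIter)
  xy
}

# ---- projection -----------------------------------------------------------

#' Project 3D points through a camera
#'
#' Pinhole projection with the rational distortion model: points in the camera
#' optical frame (mm, `+z` forward) are normalised by depth, distorted, and
#' mapped through `K`.
#'
#' @param camera a [CameraModel-class].
#' @param points N x 3 matrix (or length-3 vector) in the optical frame, mm.
#' @return N x 2 matrix of pixel coordinates `(u, v)`.
#' @export
projectPoints <- function(camera, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L, byrow = TRUE)
  points <- asPointMatrix(points)
  if (any(points[, 3] <= 0))
    stopf("cannot project points at or behind the camera (z <= 0)")
  xy <- points[, 1:2, drop = FALSE] / points[, 3]
  xyd <- distortNormalized(camera, xy)
  K <- camera@K
  cbind(K[1, 1] * xyd[, 1] + K[1, 3], K[2, 2] * xyd[, 2] + K[2, 3], deparse.level = 0)
}

#' Unproject pixels to 3D points
#'
#' Maps pixels plus z-depths back to the optical frame: pixels are normalised
#' through `K`, distortion is removed by damped fixed-point iteration, and the
#' ray is scaled so the returned z equals the given depth (z-depth convention,
#' not ray length).
#'
#' @param camera a [CameraModel-class].
#' @param pixels N x 2 matrix (or length-2 vector) of `(u, v)`.
#' @param depth z-depths in mm (length 1 or N); must be positive.
#' @param checkBounds reject pixels outside the sensor (default TRUE).
#' @return N x 3 matrix in the optical frame, mm.
#' @export
unprojectPixels <- function(camera, pixels, depth, checkBounds = TRUE) {
  pixels <- asPixelMatrix(pixels)
  depth <- rep_len(as.numeric(depth), nrow(pixels))
  if (any(depth <= 0)) stopf("depth must be positive")
  if (checkBounds) {
    if (any(pixels[, 1] < -0.5 | pixels[, 1] > camera@width - 0.5 |
            pixels[, 2] < -0.5 | pixels[, 2] > camera@height - 0.5))
      stopf("pixel outside image bounds")
  }
  K <- camera@K
  xyd <- cbind((pixels[, 1] - K[1, 3]) / K[1, 1], (pixels[, 2] - K[2, 3]) / K[2, 2])
  xy <- undistortNormalized(camera, xyd)
  cbind(xy[, 1] * depth, xy[, 2] * depth, depth, deparse.level = 0)
}

#' Apply a homography to pixel coordinates
#'
#' @param h a [Homography-class] (or plain 3x3 matrix).
#' @param pixels N x 2 matrix (or length-2 vector) of `(u, v)`.
#' @return N x 2 matrix of mapped pixels.
#' @export
applyHomography <- function(h, pixels) {
  H <- if (is(h, "Homography")) h@H else as.matrix(h)
  pixels <- asPixelMatrix(pixels)
  if (!all(is.finite(pixels))) stopf("pixels must be finite")
  P <- cbind(pixels, 1) %*% t(H)
  w <- P[, 3]
  if (any(abs(w) < 1e-12))
    stopf("point maps to the line at infinity (w ~ 0) under this homography")
  P[, 1:2, drop = FALSE] / w
}

#' Invert a homography
#' @param h a [Homography-class].
#' @return The inverse [Homography-class] (cameras swapped).
#' @export
invertHomography <- function(h)
  homography(solve(h@H), sourceCamera = h@targetCamera, targetCamera = h@sourceCamera)

# ---- Kabsch ---------------------------------------------------------------

#' Least-squares rigid fit between paired point sets
#'
#' Kabsch/Umeyama solution (rotation + translation, no scale) minimising
#' `sum || R x_i + t - y_i ||^2`.
#'
#' @param X,Y N x 3 matrices of paired points.
#' @param frameFrom,frameTo frame labels for the result.
#' @return A [RigidTransform-class] mapping X onto Y.
#' @export
kabschTransform <- function(X, Y, frameFrom = "a", frameTo = "b") {
  X <- asPointMatrix(X, "X"); Y <- asPointMatrix(Y, "Y")
  stopifnot(nrow(X) == nrow(Y), nrow(X) >= 3L)
  mx <- colMeans(X); my <- colMeans(Y)
  H <- crossprod(sweep(X, 2, mx), sweep(Y, 2, my))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  rigidTransform(R, my - R %*% mx, frameFrom, frameTo)
}
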