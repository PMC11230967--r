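#' RigidTransform: a labelled SE(3) map
#'
#' A 4x4 homogeneous rigid-body transform in millimetres, carrying the names of
#' the frame it maps from and the frame it maps to. All poses handled by the
#' package (tracked camera body `C`, camera pose from perspective-n-point `V`,
#' body-to-optical calibration `M`, per-frame registration `T`, world pose of
#' the MR model `G`) are stored in this class. Points are column vectors and
#' transforms act by left multiplication.
#'
#' @slot matrix 4x4 numeric homogeneous matrix; rotation block orthonormal with
#'   determinant +1, last row `(0, 0, 0, 1)`.
#' @slot frameFrom label of the source frame.
#' @slot frameTo label of the destination frame.
#' @seealso [rigidTransform()], [compose()], [invert()], [transformPoints()]
#' @export
setClass("RigidTransform",
  representation(matrix = "matrix", frameFrom = "character", frameTo = "character"),
  prototype(matrix = diag(4), frameFrom = "a", frameTo = "b"))

setValidity("RigidTransform", function(object) {
  m <- object@matrix
  if (!is.numeric(m) || !identical(dim(m), c(4L, 4L))) return("matrix must be 4x4 numeric")
  if (!all(is.finite(m))) return("matrix must be finite")
  if (!identical(m[4, ], c(0, 0, 0, 1))) return("last row must be exactly (0,0,0,1)")
  R <- m[1:3, 1:3]
  if (max(abs(crossprod(R) - diag(3))) > 1e-9) return("rotation block is not orthonormal (tol 1e-9)")
  if (abs(det(R) - 1) > 1e-9) return("rotation block must have det +1 (tol 1e-9)")
  if (length(object@frameFrom) != 1L || length(object@frameTo) != 1L)
    return("frame labels must be single strings")
  TRUE
})

#' Construct a RigidTransform
#'
#' @param R 3x3 rotation matrix, or a full 4x4 homogeneous matrix (in which
#'   case `t` is ignored).
#' @param t length-3 translation in mm.
#' @param frameFrom,frameTo frame labels; the transform maps points expressed
#'   in `frameFrom` into `frameTo`.
#' @return A [RigidTransform-class] object.
#' @examples
#' rigidTransform(diag(3), c(0, 0, 100), "optical", "body")
#' @export
rigidTransform <- function(R = diag(3), t = c(0, 0, 0), frameFrom = "a", frameTo = "b") {
  if (is.matrix(R) && all(dim(R) == c(4L, 4L))) {
    m <- R
  } else {
    m <- diag(4)
    m[1:3, 1:3] <- R
    m[1:3, 4] <- t
  }
  m[4, ] <- c(0, 0, 0, 1)
  new("RigidTransform", matrix = m, frameFrom = frameFrom, frameTo = frameTo)
}

#' Identity transform between two frames
#' @inheritParams rigidTransform
#' @return A [RigidTransform-class] equal to the identity.
#' @export
identityTransform <- function(frameFrom = "a", frameTo = frameFrom)
  rigidTransform(diag(3), c(0, 0, 0), frameFrom, frameTo)

#' CameraModel: pinhole intrinsics with rational distortion
#'
#' Intrinsic description of one camera of the rig (infrared/depth, RGB or
#' hyperspectral): the 3x3 intrinsic matrix `K`, the eight coefficients of the
#' rational distortion model (six radial `k1..k6` forming the rational radial
#' factor, two tangential `p1, p2`), and the sensor size in pixels. Pixel
#' convention: `(u, v) = (column, row)`, origin at the top-left pixel centre,
#' `+z` along the optical axis into the scene, `+x` right, `+y` down.
#'
#' @slot K 3x3 intrinsic matrix (fx, fy on the diagonal, principal point in the
#'   last column, zero skew).
#' @slot distortion named numeric of length 8: `k1..k6, p1, p2`.
#' @slot width,height sensor size in pixels.
#' @slot name camera label, conventionally one of `"IR"`, `"RGB"`, `"HS"`.
#' @seealso [cameraModel()], [projectPoints()], [unprojectPixels()]
#' @export
setClass("CameraModel",
  representation(K = "matrix", distortion = "numeric",
                 width = "integer", height = "integer", name = "character"))

setValidity("CameraModel", function(object) {
  K <- object@K
  if (!identical(dim(K), c(3L, 3L))) return("K must be 3x3")
  fx <- K[1, 1]; fy <- K[2, 2]; cx <- K[1, 3]; cy <- K[2, 3]
  if (!(fx > 0 && fy > 0)) return("focal lengths must be positive")
  if (length(object@distortion) != 8L) return("distortion must have 8 coefficients")
  if (object@width < 1L || object@height < 1L) return("image size must be positive")
  if (cx < 0 || cx >= object@width) return("cx must lie inside [0, width)")
  if (cy < 0 || cy >= object@height) return("cy must lie inside [0, height)")
  TRUE
})

#' Construct a CameraModel
#'
#' @param fx,fy focal lengths in pixels.
#' @param cx,cy principal point in pixels.
#' @param width,height image size in pixels.
#' @param distortion numeric of length 8, rational-model coefficients in the
#'   order `k1, k2, k3, k4, k5, k6, p1, p2` (`k1..k3` numerator, `k4..k6`
#'   denominator of the radial factor). Defaults to zero (pure pinhole).
#' @param name camera label.
#' @return A [CameraModel-class].
#' @examples
#' irCameraDefault()
#' @export
cameraModel <- function(fx, fy, cx, cy, width, height,
                        distortion = numeric(8), name = "IR") {
  K <- matrix(c(fx, 0, cx, 0, fy, cy, 0, 0, 1), 3, 3, byrow = TRUE)
  d <- as.numeric(distortion)
  names(d) <- c("k1", "k2", "k3", "k4", "k5", "k6", "p1", "p2")
  new("CameraModel", K = K, distortion = d,
      width = as.integer(width), height = as.integer(height), name = name)
}

#' Default infrared depth-camera model used by the simulator
#'
#' A 640x576 infrared camera (the native depth resolution of the emulated
#' time-of-flight device) with a 504 px focal length, principal point at the
#' image centre and no distortion.
#' @param distortion optional 8-vector of rational distortion coefficients.
#' @return A [CameraModel-class] named `"IR"`.
#' @export
irCameraDefault <- function(distortion = numeric(8))
  cameraModel(504, 504, 319.5, 287.5, 640L, 576L, distortion, "IR")

#' PointCloud: labelled points in millimetres
#'
#' @slot points N x 3 numeric matrix of coordinates in mm.
#' @slot frame frame label the coordinates are expressed in.
#' @seealso [pointCloud()], [transformPoints()]
#' @export
setClass("PointCloud", representation(points = "matrix", frame = "character"))

setValidity("PointCloud", function(object) {
  p <- object@points
  if (ncol(p) != 3L) return("points must be N x 3")
  if (nrow(p) < 1L) return("point cloud must contain at least one point")
  if (!all(is.finite(p))) return("coordinates must be finite")
  TRUE
})

#' Construct a PointCloud
#' @param points N x 3 matrix (mm).
#' @param frame frame label.
#' @return A [PointCloud-class].
#' @export
pointCloud <- function(points, frame = "unknown")
  new("PointCloud", points = asPointMatrix(points), frame = frame)

#' Homography: projective map between two image planes
#'
#' @slot H 3x3 matrix, canonicalised so `H[3, 3] = 1`.
#' @slot sourceCamera,targetCamera camera labels.
#' @seealso [homography()], [applyHomography()], [estimateHomography()]
#' @export
setClass("Homography",
  representation(H = "matrix", sourceCamera = "character", targetCamera = "character"))

setValidity("Homography", function(object) {
  H <- object@H
  if (!identical(dim(H), c(3L, 3L))) return("H must be 3x3")
  if (!all(is.finite(H))) return("H must be finite")
  if (abs(H[3, 3] - 1) > 1e-12) return("H must be canonicalised with H[3,3] = 1")
  if (abs(det(H)) < 1e-15) return("H must be invertible")
  TRUE
})

#' Construct a Homography
#' @param H 3x3 matrix (any nonzero scale; canonicalised internally).
#' @param sourceCamera,targetCamera camera labels.
#' @return A [Homography-class].
#' @export
homography <- function(H, sourceCamera = "IR", targetCamera = "RGB") {
  H <- as.matrix(H)
  if (abs(H[3, 3]) < 1e-15) stopf("H[3,3] is (near) zero; cannot canonicalise")
  new("Homography", H = H / H[3, 3],
      sourceCamera = sourceCamera, targetCamera = targetCamera)
}

#' MRSurface: head surface extracted from the preoperative MR
#'
#' @slot vertices N x 3 matrix in scanner mm (RAS).
#' @slot triangles M x 3 integer matrix of 1-based vertex indices (may have
#'   zero rows when only points are available).
#' @slot provenance `"nifti-isosurface"`, `"mesh-file"` or `"synthetic"`.
#' @seealso [surfaceFromVolume()], [readMr()], [extractMrFace()]
#' @export
setClass("MRSurface",
  representation(vertices = "matrix", triangles = "matrix", provenance = "character"))

setValidity("MRSurface", function(object) {
  if (ncol(object@vertices) != 3L) return("vertices must be N x 3")
  if (!all(is.finite(object@vertices))) return("vertices must be finite")
  if (nrow(object@triangles) > 0L) {
    if (ncol(object@triangles) != 3L) return("triangles must be M x 3")
    if (min(object@triangles) < 1L || max(object@triangles) > nrow(object@vertices))
      return("triangle indices out of range")
  }
  TRUE
})

#' Construct an MRSurface
#' @param vertices N x 3 matrix (mm).
#' @param triangles optional M x 3 integer matrix of 1-based indices.
#' @param provenance provenance label.
#' @return An [MRSurface-class].
#' @export
mrSurface <- function(vertices, triangles = matrix(integer(0), 0, 3), provenance = "synthetic") {
  tr <- as.matrix(triangles); storage.mode(tr) <- "integer"
  new("MRSurface", vertices = asPointMatrix(vertices, "vertices"),
      triangles = tr, provenance = provenance)
}

#' DepthFrame: one depth capture in millimetres
#'
#' @slot depth numeric matrix `[height, width]` of z-depths in mm; 0 marks an
#'   invalid pixel and is excluded from every statistic.
#' @slot camera the [CameraModel-class] of the depth (IR) camera.
#' @slot timestamp acquisition time in seconds (arbitrary origin).
#' @export
setClass("DepthFrame",
  representation(depth = "matrix", camera = "CameraModel", timestamp = "numeric"))

setValidity("DepthFrame", function(object) {
  d <- object@depth
  if (!all(is.finite(d))) return("depth must be finite")
  if (any(d < 0)) return("depth must be non-negative (0 = invalid)")
  if (nrow(d) != object@camera@height || ncol(d) != object@camera@width)
    return("depth dimensions must match the camera model")
  TRUE
})

#' Construct a DepthFrame
#' @param depth matrix `[height, width]` of mm, 0 = invalid.
#' @param camera [CameraModel-class] of the depth camera.
#' @param timestamp seconds.
#' @return A [DepthFrame-class].
#' @export
depthFrame <- function(depth, camera, timestamp = 0) {
  storage.mode(depth) <- "double"
  new("DepthFrame", depth = depth, camera = camera, timestamp = as.numeric(timestamp))
}

#' DepthCorrection: polynomial depth-bias correction
#'
#' Maps raw sensor depth (mm) to corrected depth (mm) through a polynomial
#' fitted on plane-sweep measurements. Identity is `coefficients = c(0, 1)`.
#'
#' @slot coefficients polynomial coefficients, ascending order (intercept first).
#' @slot fitRange `(min, max)` raw-depth range covered by the fit, mm.
#' @slot residualRmse residual RMSE of the fit, mm.
#' @slot stdErrors standard errors of the coefficients (same order).
#' @seealso [fitDepthCorrection()], [applyDepthCorrection()]
#' @export
setClass("DepthCorrection",
  representation(coefficients = "numeric", fitRange = "numeric",
                 residualRmse = "numeric", stdErrors = "numeric"))

setValidity("DepthCorrection", function(object) {
  if (length(object@coefficients) < 2L) return("need at least intercept and slope")
  if (length(object@fitRange) != 2L || object@fitRange[1] >= object@fitRange[2])
    return("fitRange must be (min, max) with min < max")
  if (object@residualRmse < 0) return("residual RMSE must be >= 0")
  TRUE
})

#' Identity depth correction over a range
#' @param range `(min, max)` raw-depth validity range in mm.
#' @return A [DepthCorrection-class] that leaves depths unchanged.
#' @export
identityDepthCorrection <- function(range = c(100, 2000))
  new("DepthCorrection", coefficients = c(0, 1), fitRange = as.numeric(range),
      residualRmse = 0, stdErrors = c(0, 0))

#' FaceROI: face bounding box in pixel coordinates
#'
#' @slot bbox `(uMin, vMin, uMax, vMax)` in pixels.
#' @slot source one of `"oracle"`, `"external-detector"`, `"file"`.
#' @export
setClass("FaceROI", representation(bbox = "numeric", source = "character"))

setValidity("FaceROI", function(object) {
  b <- object@bbox
  if (length(b) != 4L || !all(is.finite(b))) return("bbox must be 4 finite numbers")
  if (!(b[1] < b[3] && b[2] < b[4])) return("bbox must satisfy uMin < uMax and vMin < vMax")
  TRUE
})

#' Construct a FaceROI
#' @param bbox `(uMin, vMin, uMax, vMax)` pixels.
#' @param source provenance of the box.
#' @return A [FaceROI-class].
#' @export
faceROI <- function(bbox, source = "file")
  new("FaceROI", bbox = as.numeric(bbox), source = source)

#' MarkerObservation: saturated-marker detections in one IR image
#'
#' @slot centroids N x 2 matrix of sub-pixel `(u, v)` blob centroids.
#' @slot pixelCounts per-blob saturated-pixel counts.
#' @slot mergedSuspect logical per blob: area is an outlier, suggesting two
#'   markers merged into one component.
#' @seealso [detectMarkers()]
#' @export
setClass("MarkerObservation",
  representation(centroids = "matrix", pixelCounts = "integer", mergedSuspect = "logical"))

#' CalibrationCapture: one tracked capture of the linear marker tool
#'
#' @slot irImage numeric matrix `[height, width]`, intensities in `[0, 1]`
#'   (1 = sensor saturation).
#' @slot cameraBodyPose [RigidTransform-class] `C` (tracker world <- camera body).
#' @slot toolMarkerPositions N x 3 matrix of marker centres in tracker world, mm.
#' @seealso [calibrateTracking()], [renderCalibrationCapture()]
#' @export
setClass("CalibrationCapture",
  representation(irImage = "matrix", cameraBodyPose = "RigidTransform",
                 toolMarkerPositions = "matrix"))

setValidity("CalibrationCapture", function(object) {
  if (nrow(object@toolMarkerPositions) < 1L) return("need at least one tool marker")
  if (ncol(object@toolMarkerPositions) != 3L) return("tool markers must be N x 3")
  TRUE
})

#' TrackingCalibration: the fixed body-to-optical transform M
#'
#' @slot M [RigidTransform-class] (camera body <- IR optical frame).
#' @slot rmsePerCapture per-capture reprojection RMSE in pixels, computed with
#'   the final `M`.
#' @slot nCaptures number of captures used.
#' @seealso [calibrateTracking()], [reprojectionRmse()]
#' @export
setClass("TrackingCalibration",
  representation(M = "RigidTransform", rmsePerCapture = "numeric", nCaptures = "integer"))

#' CornerGrid: ordered chessboard corners from one camera
#'
#' @slot corners N x 2 matrix of sub-pixel `(u, v)` corners, row-major over the
#'   grid (all columns of row 1, then row 2, ...).
#' @slot gridRows,gridCols grid shape; `gridRows * gridCols == nrow(corners)`.
#' @slot camera camera label.
#' @export
setClass("CornerGrid",
  representation(corners = "matrix", gridRows = "integer", gridCols = "integer",
                 camera = "character"))

setValidity("CornerGrid", function(object) {
  if (ncol(object@corners) != 2L) return("corners must be N x 2")
  if (object@gridRows * object@gridCols != nrow(object@corners))
    return("gridRows * gridCols must equal the corner count")
  TRUE
})

#' Construct a CornerGrid
#' @param corners N x 2 matrix of `(u, v)` corners, row-major grid order.
#' @param gridRows,gridCols grid shape.
#' @param camera camera label.
#' @return A [CornerGrid-class].
#' @export
cornerGrid <- function(corners, gridRows, gridCols, camera = "IR")
  new("CornerGrid", corners = asPixelMatrix(corners, "corners"),
      gridRows = as.integer(gridRows), gridCols = as.integer(gridCols), camera = camera)

#' HomographyFit: estimated homography with its reprojection RMSE
#'
#' @slot homography the estimated [Homography-class].
#' @slot rmse reprojection RMSE in pixels over the points used.
#' @slot nPoints number of point pairs.
#' @seealso [estimateHomography()]
#' @export
setClass("HomographyFit",
  representation(homography = "Homography", rmse = "numeric", nPoints = "integer"))

setValidity("HomographyFit", function(object) {
  if (object@rmse < 0) return("rmse must be >= 0")
  if (object@nPoints < 4L) return("a homography fit needs at least 4 points")
  TRUE
})

#' RegistrationResult: one frame of MR-to-camera registration
#'
#' @slot T [RigidTransform-class] (MR <- IR optical) for the frame.
#' @slot icpRmse final inlier RMSE of the ICP, mm.
#' @slot nIterations ICP iterations run.
#' @slot converged whether the relative RMSE change fell below tolerance.
#' @slot inlierFraction RANSAC inlier fraction (NA when ICP was warm-started).
#' @seealso [icpRefine()], [registerStream()], [chainWorldPose()]
#' @export
setClass("RegistrationResult",
  representation(T = "RigidTransform", icpRmse = "numeric", nIterations = "integer",
                 converged = "logical", inlierFraction = "numeric"))

#' PoseFilterState: error-state Kalman filter over SE(3) poses
#'
#' Constant-pose process model: translation filtered linearly, orientation
#' filtered multiplicatively on the quaternion error state (rotation vector).
#'
#' @slot translation filtered translation mean, mm.
#' @slot Pt 3x3 translation covariance, mm^2.
#' @slot quaternion filtered orientation `(w, x, y, z)`, unit norm.
#' @slot Pq 3x3 orientation error-state covariance, rad^2.
#' @slot processNoise `(translation mm^2/frame, rotation rad^2/frame)` added at
#'   each predict step.
#' @slot measurementNoise `(translation mm^2, rotation rad^2)` of one pose
#'   measurement.
#' @slot initialized whether a first measurement has been absorbed.
#' @seealso [poseFilter()], [kalmanUpdate()]
#' @export
setClass("PoseFilterState",
  representation(translation = "numeric", Pt = "matrix", quaternion = "numeric",
                 Pq = "matrix", processNoise = "numeric", measurementNoise = "numeric",
                 initialized = "logical"))

#' ErrorReport: per-trial registration error metric
#'
#' @slot metric `"FRE"`, `"TRE"` or `"RRE"`.
#' @slot values per-trial values, mm.
#' @seealso [runGridExperiment()]
#' @export
setClass("ErrorReport", representation(metric = "character", values = "numeric"))

setValidity("ErrorReport", function(object) {
  if (any(object@values < 0)) return("error values must be >= 0")
  TRUE
})

#' Construct an ErrorReport
#' @param metric metric name.
#' @param values per-trial values in mm.
#' @return An [ErrorReport-class].
#' @export
errorReport <- function(metric, values)
  new("ErrorReport", metric = metric, values = as.numeric(values))
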