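#' @include AllClasses.R
NULL

#' Compose two rigid transforms
#'
#' `compose(A, B)` is the transform that first applies `B`, then `A`
#' (matrix product `A %*% B`); frame labels must chain
#' (`frameFrom(A) == frameTo(B)`) and are propagated.
#'
#' @param A,B [RigidTransform-class] objects.
#' @return A [RigidTransform-class] mapping `frameFrom(B)` to `frameTo(A)`.
#' @export
setGeneric("compose", function(A, B) standardGeneric("compose"))

#' Invert a rigid transform
#'
#' @param A a [RigidTransform-class].
#' @return The inverse transform, with frame labels swapped.
#' @export
setGeneric("invert", function(A) standardGeneric("invert"))

#' Apply a rigid transform to points
#'
#' @param A a [RigidTransform-class].
#' @param x an N x 3 matrix or a [PointCloud-class]. For a cloud the frame
#'   label must match `frameFrom(A)` and the result carries `frameTo(A)`.
#' @return Same shape as `x`, transformed.
#' @export
setGeneric("transformPoints", function(A, x) standardGeneric("transformPoints"))

#' @rdname accessors
#' @export
setGeneric("transformMatrix", function(x) standardGeneric("transformMatrix"))
#' @rdname accessors
#' @export
setGeneric("frameFrom", function(x) standardGeneric("frameFrom"))
#' @rdname accessors
#' @export
setGeneric("frameTo", function(x) standardGeneric("frameTo"))
#' @rdname accessors
#' @export
setGeneric("cloudPoints", function(x) standardGeneric("cloudPoints"))
#' @rdname accessors
#' @export
setGeneric("cloudFrame", function(x) standardGeneric("cloudFrame"))
#' @rdname accessors
#' @export
setGeneric("intrinsicMatrix", function(x) standardGeneric("intrinsicMatrix"))
#' @rdname accessors
#' @export
setGeneric("distortionCoefficients", function(x) standardGeneric("distortionCoefficients"))
#' @rdname accessors
#' @export
setGeneric("imageSize", function(x) standardGeneric("imageSize"))
#' @rdname accessors
#' @export
setGeneric("cameraName", function(x) standardGeneric("cameraName"))
#' @rdname accessors
#' @export
setGeneric("homographyMatrix", function(x) standardGeneric("homographyMatrix"))
#' @rdname accessors
#' @export
setGeneric("vertices", function(x) standardGeneric("vertices"))
#' @rdname accessors
#' @export
setGeneric("triangles", function(x) standardGeneric("triangles"))
#' @rdname accessors
#' @export
setGeneric("depthValues", function(x) standardGeneric("depthValues"))
#' @rdname accessors
#' @export
setGeneric("trackingMatrix", function(x) standardGeneric("trackingMatrix"))
#' @rdname accessors
#' @export
setGeneric("registrationTransform", function(x) standardGeneric("registrationTransform"))
#' @rdname accessors
#' @export
setGeneric("errorValues", function(x) standardGeneric("errorValues"))

#' Accessors for SurfNav classes
#'
#' Read-only accessors for the slots of the package's S4 classes; user code
#' should use these rather than `@`.
#'
#' @param x an object of the matching class.
#' @return The slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("transformMatrix", "RigidTransform", function(x) x@matrix)
#' @rdname accessors
#' @export
setMethod("frameFrom", "RigidTransform", function(x) x@frameFrom)
#' @rdname accessors
#' @export
setMethod("frameTo", "RigidTransform", function(x) x@frameTo)
#' @rdname accessors
#' @export
setMethod("cloudPoints", "PointCloud", function(x) x@points)
#' @rdname accessors
#' @export
setMethod("cloudFrame", "PointCloud", function(x) x@frame)
#' @rdname accessors
#' @export
setMethod("intrinsicMatrix", "CameraModel", function(x) x@K)
#' @rdname accessors
#' @export
setMethod("distortionCoefficients", "CameraModel", function(x) x@distortion)
#' @rdname accessors
#' @export
setMethod("imageSize", "CameraModel", function(x) c(width = x@width, height = x@height))
#' @rdname accessors
#' @export
setMethod("cameraName", "CameraModel", function(x) x@name)
#' @rdname accessors
#' @export
setMethod("homographyMatrix", "Homography", function(x) x@H)
#' @rdname accessors
#' @export
setMethod("vertices", "MRSurface", function(x) x@vertices)
#' @rdname accessors
#' @export
setMethod("triangles", "MRSurface", function(x) x@triangles)
#' @rdname accessors
#' @export
setMethod("depthValues", "DepthFrame", function(x) x@depth)
#' @rdname accessors
#' @export
setMethod("trackingMatrix", "TrackingCalibration", function(x) x@M)
#' @rdname accessors
#' @export
setMethod("registrationTransform", "RegistrationResult", function(x) x@T)
#' @rdname accessors
#' @export
setMethod("errorValues", "ErrorReport", function(x) x@values)

setMethod("show", "RigidTransform", function(object) {
  cat(sprintf("RigidTransform: %s <- %s\n", object@frameTo, object@frameFrom))
  print(round(object@matrix, 6))
})

setMethod("show", "CameraModel", function(object) {
  K <- object@K
  cat(sprintf("CameraModel '%s': %dx%d px, fx=%.1f fy=%.1f cx=%.1f cy=%.1f\n",
              object@name, object@width, object@height, K[1, 1], K[2, 2], K[1, 3], K[2, 3]))
  if (any(object@distortion != 0))
    cat("  distortion:", paste(sprintf("%s=%.3g", names(object@distortion),
                                       object@distortion), collapse = " "), "\n")
  else cat("  distortion: none\n")
})

setMethod("show", "PointCloud", function(object) {
  cat(sprintf("PointCloud: %d points in frame '%s'\n", nrow(object@points), object@frame))
})

setMethod("show", "Homography", function(object) {
  cat(sprintf("Homography: %s -> %s\n", object@sourceCamera, object@targetCamera))
  print(round(object@H, 6))
})

setMethod("show", "MRSurface", function(object) {
  cat(sprintf("MRSurface: %d vertices, %d triangles (%s)\n",
              nrow(object@vertices), nrow(object@triangles), object@provenance))
})

setMethod("show", "DepthFrame", function(object) {
  d <- object@depth
  v <- d[d > 0]
  cat(sprintf("DepthFrame: %dx%d, %d valid px, depth %s mm, t=%.3f s\n",
              ncol(d), nrow(d), length(v),
              if (length(v)) sprintf("[%.0f, %.0f]", min(v), max(v)) else "[-]",
              object@timestamp))
})

setMethod("show", "TrackingCalibration", function(object) {
  cat(sprintf("TrackingCalibration from %d captures; reprojection RMSE %.3f px (mean)\n",
              object@nCaptures, mean(object@rmsePerCapture)))
  show(object@M)
})

setMethod("show", "RegistrationResult", function(object) {
  cat(sprintf("RegistrationResult: ICP RMSE %.4f mm in %d iterations (%s)\n",
              object@icpRmse, object@nIterations,
              if (object@converged) "converged" else "not converged"))
})

setMethod("show", "ErrorReport", function(object) {
  v <- object@values
  cat(sprintf("%s over %d trials: %.3f +/- %.3f mm\n",
              object@metric, length(v), mean(v), if (length(v) > 1) sd(v) else 0))
})

setMethod("show", "DepthCorrection", function(object) {
  cat(sprintf("DepthCorrection: degree %d, range [%.0f, %.0f] mm, residual RMSE %.3f mm\n",
              length(object@coefficients) - 1L, object@fitRange[1], object@fitRange[2],
              object@residualRmse))
})

#' Summary statistics of an ErrorReport
#' @param object an [ErrorReport-class].
#' @param ... ignored.
#' @return Named list with `metric`, `mean`, `sd`, `n`, `values`.
#' @export
setMethod("summary", "ErrorReport", function(object, ...) {
  v <- object@values
  list(metric = object@metric, mean = mean(v),
       sd = if (length(v) > 1) sd(v) else 0, n = length(v), values = v)
})
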