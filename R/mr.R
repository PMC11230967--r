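#' @include geometry.R
NULL

#' Extract an isosurface from an MR volume
#'
#' Marching-tetrahedra isosurface at the given threshold; vertices are placed
#' on voxel edges by linear interpolation, scaled to mm by the voxel spacing
#' (or mapped through a full affine when one is supplied), and only the
#' largest connected component is kept.
#'
#' @param volume 3D numeric array of intensities.
#' @param spacing voxel spacing in mm, length 3 (ignored when `affine` given).
#' @param isoThreshold intensity level of the surface.
#' @param affine optional 4x4 voxel-index (0-based) to mm affine; used to
#'   honour scanner orientation from NIfTI headers.
#' @param largestOnly keep only the largest connected component (default TRUE).
#' @return An [MRSurface-class] with provenance `"nifti-isosurface"`.
#' @export
surfaceFromVolume <- function(volume, spacing = c(1, 1, 1), isoThreshold,
                              affine = NULL, largestOnly = TRUE) {
  if (is.null(affine) && any(spacing <= 0)) stopf("voxel spacings must be positive")
  rng <- range(volume)
  if (isoThreshold <= rng[1] || isoThreshold >= rng[2])
    stopf("iso-threshold %g produces an empty isosurface (intensity range [%g, %g])",
          isoThreshold, rng[1], rng[2])
  res <- cpp_marching_tetrahedra(as.numeric(volume), dim(volume), isoThreshold,
                                 largestOnly)
  if (nrow(res$V) == 0L) stopf("iso-threshold %g produces an empty isosurface", isoThreshold)
  V <- res$V
  if (!is.null(affine)) {
    V <- cbind(V, 1) %*% t(affine)
    V <- V[, 1:3, drop = FALSE]
  } else {
    V <- sweep(V, 2L, spacing, "*")
  }
  mrSurface(V, res$F, provenance = "nifti-isosurface")
}

#' Align an MR surface to a virtual camera by principal components
#'
#' Computes the principal axes of the surface points. The first component (the
#' long head axis) becomes the camera up direction (image `-y`), the second
#' (the front-back axis through the nose) becomes the optical axis, with its
#' sign fixed so that the nose side faces the camera: the nose is the dominant
#' asymmetry, so the sign is chosen from the skewness of the projections onto
#' the axis (the heavy positive tail points at the nose). The returned
#' transform maps MR coordinates into a virtual camera frame (`+z` into the
#' scene, `+y` down) with the centroid on the optical axis at `viewDistance`.
#'
#' @param surface an [MRSurface-class] or [PointCloud-class].
#' @param viewDistance standoff of the virtual camera from the centroid, mm.
#' @param isotropyTol minimum allowed ratio between consecutive eigenvalues;
#'   below it the orientation is ambiguous and an error is raised.
#' @return List with `transform` (a [RigidTransform-class], virtual camera <-
#'   MR), `principalAxes` (rows = components, descending variance) and
#'   `centroid` (mm).
#' @export
pcaAlign <- function(surface, viewDistance = 600, isotropyTol = 1.05) {
  pts <- if (is(surface, "MRSurface")) surface@vertices else surface@points
  if (nrow(pts) < 10L) stopf("too few points for PCA alignment")
  ctr <- colMeans(pts)
  Xc <- sweep(pts, 2, ctr)
  ev <- eigen(crossprod(Xc) / nrow(Xc), symmetric = TRUE)
  lam <- ev$values
  if (lam[1] / lam[2] < isotropyTol || lam[2] / lam[3] < isotropyTol)
    stopf(paste("ambiguous orientation: eigenvalue ratios %.3f / %.3f are below %.2f;",
                "the surface has no dominant axes"),
          lam[1] / lam[2], lam[2] / lam[3], isotropyTol)
  e1 <- ev$vectors[, 1]; e2 <- ev$vectors[, 2]
  skew <- function(v) {
    t <- Xc %*% v
    mean(t^3) / (mean(t^2)^1.5)
  }
  # nose = heavy positive tail along PC2
  if (skew(e2) < 0) e2 <- -e2
  # chin/nose-ward side of the long axis hangs down in the image (+y is down)
  if (skew(e1) < 0) e1 <- -e1
  zc <- -e2                      # optical axis points from camera into the face
  yc <- e1
  # re-orthogonalise y against z (numerically they already are), then x = y x z
  yc <- yc - sum(yc * zc) * zc
  yc <- yc / sqrt(sum(yc^2))
  xc <- c(yc[2] * zc[3] - yc[3] * zc[2],
          yc[3] * zc[1] - yc[1] * zc[3],
          yc[1] * zc[2] - yc[2] * zc[1])
  R <- rbind(xc, yc, zc)
  dimnames(R) <- NULL
  transform <- rigidTransform(R, c(0, 0, viewDistance) - R %*% ctr,
                              frameFrom = "MR", frameTo = "virtual")
  axes <- rbind(e1, e2, xc)  # descending-variance components as rows
  dimnames(axes) <- NULL
  list(transform = transform, principalAxes = axes, centroid = ctr)
}

#' Hidden point removal by spherical flipping
#'
#' Katz-style visibility for point clouds: each point is flipped radially
#' about the viewpoint, `p' = p + 2 (R - |p|) p / |p|` with
#' `R = radiusFactor * max |p|`, and the points whose flipped images lie on
#' the convex hull of the flipped set united with the viewpoint are declared
#' visible.
#'
#' @param cloud a [PointCloud-class] or N x 3 matrix.
#' @param viewpoint length-3 camera position in the cloud's frame, mm.
#' @param radiusFactor sphere radius as a multiple of the maximal distance to
#'   the viewpoint; must be > 1 (default 100).
#' @return Integer vector of visible point indices (1-based, ascending).
#' @export
hiddenPointRemoval <- function(cloud, viewpoint = c(0, 0, 0), radiusFactor = 100) {
  pts <- if (is(cloud, "PointCloud")) cloud@points else asPointMatrix(cloud)
  if (nrow(pts) < 4L) return(seq_len(nrow(pts)))
  if (radiusFactor <= 1) stopf("invalid radius: radiusFactor must exceed 1 (R > max |p|)")
  q <- sweep(pts, 2, viewpoint)
  nrm <- sqrt(rowSums(q^2))
  if (any(nrm < 1e-9)) stopf("a point coincides with the viewpoint")
  R <- radiusFactor * max(nrm)
  flipped <- q + 2 * (R - nrm) * q / nrm
  hull <- cpp_convex_hull_vertices(rbind(flipped, c(0, 0, 0)))
  sort(hull[hull <= nrow(pts)])
}

#' Extract the camera-facing MR face surface
#'
#' Pipeline: PCA alignment to the virtual camera, transform of the surface
#' points, hidden point removal from the camera origin, and return of the
#' visible subset.
#'
#' @inheritParams pcaAlign
#' @param radiusFactor hidden-point-removal radius factor.
#' @return List with `cloud` (a [PointCloud-class] in frame `"virtual"`),
#'   `alignment` (the [pcaAlign()] result) and `visible` (indices into the
#'   surface vertices).
#' @export
extractMrFace <- function(surface, viewDistance = 600, radiusFactor = 100,
                          isotropyTol = 1.05) {
  alignment <- pcaAlign(surface, viewDistance, isotropyTol)
  pts <- if (is(surface, "MRSurface")) surface@vertices else surface@points
  aligned <- transformPoints(alignment$transform, pts)
  visible <- hiddenPointRemoval(aligned, c(0, 0, 0), radiusFactor)
  list(cloud = pointCloud(aligned[visible, , drop = FALSE], frame = "virtual"),
       alignment = alignment, visible = visible)
}
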