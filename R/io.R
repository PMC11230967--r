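#' @include AllClasses.R io-ply.R io-npy.R
NULL

#' Read and write the shared calibration file
#'
#' A single JSON file carries every calibration artefact of the rig: the
#' per-camera intrinsics (`cameras`: name, width, height, K row-major,
#' distortion), the inter-camera homographies (`homographies`: source,
#' target, H row-major), the tracking calibration (`tracking_calibration`:
#' M row-major, per-capture RMSE) and the depth correction
#' (`depth_correction`: degree, coefficients, range, rmse). Sections are
#' optional; [writeCalibration()] merges into an existing file.
#'
#' @param path JSON file path.
#' @return `readCalibration`: a list with `cameras` (named list of
#'   [CameraModel-class]), `homographies` (list of [Homography-class]),
#'   `M` ([RigidTransform-class] or NULL), `depthCorrection`
#'   ([DepthCorrection-class] or NULL).
#' @export
readCalibration <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                           simplifyMatrix = FALSE)
  cameras <- list()
  for (cm in j$cameras) {
    K <- matrix(unlist(cm$K), 3, 3, byrow = TRUE)
    cameras[[cm$name]] <- cameraModel(K[1, 1], K[2, 2], K[1, 3], K[2, 3],
                                      cm$width, cm$height,
                                      unlist(cm$distortion), cm$name)
  }
  homographies <- lapply(j$homographies, function(h)
    homography(matrix(unlist(h$H), 3, 3, byrow = TRUE), h$source, h$target))
  M <- if (!is.null(j$tracking_calibration))
    rigidTransform(matrix(unlist(j$tracking_calibration$M), 4, 4, byrow = TRUE),
                   frameFrom = "optical", frameTo = "body") else NULL
  dc <- if (!is.null(j$depth_correction))
    new("DepthCorrection",
        coefficients = unlist(j$depth_correction$coefficients),
        fitRange = unlist(j$depth_correction$range),
        residualRmse = j$depth_correction$rmse,
        stdErrors = rep(0, length(unlist(j$depth_correction$coefficients)))) else NULL
  list(cameras = cameras, homographies = homographies, M = M, depthCorrection = dc)
}

#' @rdname readCalibration
#' @param cameras named list of [CameraModel-class] (optional).
#' @param homographies list of [Homography-class] or [HomographyFit-class].
#' @param M a [RigidTransform-class] or [TrackingCalibration-class].
#' @param depthCorrection a [DepthCorrection-class].
#' @param merge merge with an existing file at `path` (default TRUE).
#' @export
writeCalibration <- function(path, cameras = NULL, homographies = NULL, M = NULL,
                             depthCorrection = NULL, merge = TRUE) {
  j <- if (merge && file.exists(path))
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                        simplifyMatrix = FALSE) else list()
  if (!is.null(cameras))
    j$cameras <- unname(lapply(cameras, function(cm) list(
      name = cm@name, width = cm@width, height = cm@height,
      K = as.numeric(t(cm@K)), distortion = unname(cm@distortion))))
  if (!is.null(homographies))
    j$homographies <- unname(lapply(homographies, function(h) {
      if (is(h, "HomographyFit")) h <- h@homography
      list(source = h@sourceCamera, target = h@targetCamera,
           H = as.numeric(t(h@H)))
    }))
  if (!is.null(M)) {
    rmse <- NULL
    if (is(M, "TrackingCalibration")) { rmse <- M@rmsePerCapture; M <- M@M }
    j$tracking_calibration <- list(M = as.numeric(t(transformMatrix(M))),
                                   rmse_per_capture = rmse)
  }
  if (!is.null(depthCorrection))
    j$depth_correction <- list(
      degree = length(depthCorrection@coefficients) - 1L,
      coefficients = depthCorrection@coefficients,
      range = depthCorrection@fitRange,
      rmse = depthCorrection@residualRmse)
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an MR head model
#'
#' NIfTI volumes (`.nii`, `.nii.gz`) are read with their affine honoured
#' (surfaces are expressed in scanner mm) and converted to a surface by
#' marching tetrahedra at `isoThreshold`; mesh files (`.ply`) pass through.
#'
#' @param path input file.
#' @param isoThreshold isosurface level for volumes; default half-way between
#'   the intensity extremes.
#' @return An [MRSurface-class].
#' @export
readMr <- function(path, isoThreshold = NULL) {
  if (!file.exists(path)) stopf("file not found: '%s'", path)
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    img <- RNifti::readNifti(path)
    vol <- as.array(img)
    if (length(dim(vol)) != 3L) stopf("expected a 3D NIfTI volume")
    aff <- structure(RNifti::xform(img), class = NULL)
    if (abs(det(aff[1:3, 1:3])) < 1e-12) stopf("non-invertible NIfTI affine")
    if (is.null(isoThreshold)) isoThreshold <- mean(range(vol))
    surfaceFromVolume(vol, isoThreshold = isoThreshold, affine = aff)
  } else if (grepl("\\.ply$", lower)) {
    out <- readPly(path)
    if (is(out, "PointCloud")) mrSurface(out@points, provenance = "mesh-file") else out
  } else stopf("unknown MR input extension in '%s' (use .nii, .nii.gz or .ply)", path)
}

#' Read a simulated (or recorded) capture bundle
#'
#' Loads the on-disk layout written by [simulateSession()].
#'
#' @param dir bundle directory.
#' @param camera the depth [CameraModel-class] used to interpret the frames.
#' @return List with `frames` (each: `frame`, `roi`, `C`), `surface`, and
#'   `groundTruth` (parsed JSON or NULL).
#' @export
readCaptureBundle <- function(dir, camera = irCameraDefault()) {
  depths <- sort(list.files(file.path(dir, "captures"), "_depth\\.npy$",
                            full.names = TRUE))
  if (length(depths) == 0L) stopf("no depth frames found under '%s'", dir)
  frames <- lapply(depths, function(f) {
    meta <- jsonlite::read_json(sub("_depth\\.npy$", "_poses.json", f),
                                simplifyVector = TRUE)
    list(frame = depthFrame(readNpy(f), camera, meta$timestamp),
         roi = faceROI(meta$roi, source = "file"),
         C = rigidTransform(matrix(meta$C, 4, 4, byrow = TRUE),
                            frameFrom = "body", frameTo = "tracker"))
  })
  surf <- readPly(file.path(dir, "mr", "head_surface.ply"))
  gt <- NULL
  gtPath <- file.path(dir, "ground_truth.json")
  if (file.exists(gtPath)) gt <- jsonlite::read_json(gtPath, simplifyVector = TRUE)
  list(frames = frames, surface = surf, groundTruth = gt)
}

#' Read and write tracking-calibration capture bundles
#'
#' Layout: `NNN_ir.npy` (IR intensity image, `[0, 1]`) plus `NNN_poses.json`
#' holding the tracked camera-body pose (`C`, 16 floats row-major) and the
#' tool marker positions (`tool_markers`, N x 3, tracker mm).
#'
#' @param captures list of [CalibrationCapture-class].
#' @param dir bundle directory.
#' @return `writeTrackingCaptures`: `dir` invisibly; `readTrackingCaptures`:
#'   a list of [CalibrationCapture-class].
#' @export
writeTrackingCaptures <- function(captures, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(captures)) {
    cap <- captures[[i]]
    writeNpy(cap@irImage, file.path(dir, sprintf("%03d_ir.npy", i)))
    jsonlite::write_json(
      list(C = as.numeric(t(transformMatrix(cap@cameraBodyPose))),
           tool_markers = unname(apply(cap@toolMarkerPositions, 1, as.numeric,
                                       simplify = FALSE))),
      file.path(dir, sprintf("%03d_poses.json", i)), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' @rdname writeTrackingCaptures
#' @export
readTrackingCaptures <- function(dir) {
  files <- sort(list.files(dir, "_ir\\.npy$", full.names = TRUE))
  if (length(files) == 0L) stopf("no IR captures found under '%s'", dir)
  lapply(files, function(f) {
    meta <- jsonlite::read_json(sub("_ir\\.npy$", "_poses.json", f),
                                simplifyVector = TRUE)
    tm <- meta$tool_markers
    tm <- if (is.list(tm)) do.call(rbind, lapply(tm, unlist))
          else if (is.matrix(tm)) tm
          else matrix(tm, ncol = 3, byrow = TRUE)
    storage.mode(tm) <- "double"
    new("CalibrationCapture", irImage = readNpy(f),
        cameraBodyPose = rigidTransform(matrix(meta$C, 4, 4, byrow = TRUE),
                                        frameFrom = "body", frameTo = "tracker"),
        toolMarkerPositions = tm)
  })
}

#' Read and write chessboard-corner CSV files
#'
#' Columns: `camera, shot, row, col, u, v` with row-major corner ordering
#' consistent across the cameras of one shot.
#'
#' @param corners data frame with the columns above.
#' @param path CSV path.
#' @return `readCornerCsv`: the data frame; `writeCornerCsv`: `path`.
#' @export
writeCornerCsv <- function(corners, path) {
  write.csv(corners, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCornerCsv
#' @export
readCornerCsv <- function(path) {
  df <- read.csv(path)
  need <- c("camera", "shot", "row", "col", "u", "v")
  if (!all(need %in% names(df)))
    stopf("corner CSV must have columns %s", paste(need, collapse = ", "))
  df
}

#' Export a static overlay of the registered MR surface onto a camera image
#'
#' Projects the registered MR face points into the target camera view
#' (through the IR-to-target homography when one is given) and composes a
#' mask overlay written as PNG, plus the projected points as a PLY scene
#' file.
#'
#' @param faceCloudOptical a [PointCloud-class] of MR face points expressed in
#'   the IR optical frame (i.e. after applying `T^-1`).
#' @param image background image matrix `[height, width]`, values in `[0, 1]`.
#' @param camera the IR [CameraModel-class].
#' @param h optional IR-to-target [Homography-class] (e.g. IR to HS); identity
#'   when NULL.
#' @param pathPng,pathPly output paths (either may be NULL to skip).
#' @return List with the overlay `mask` (logical matrix) and the projected
#'   `pixels`, invisibly.
#' @export
exportOverlay <- function(faceCloudOptical, image, camera, h = NULL,
                          pathPng = NULL, pathPly = NULL) {
  pts <- faceCloudOptical@points
  pts <- pts[pts[, 3] > 0, , drop = FALSE]
  uv <- projectPoints(camera, pts)
  if (!is.null(h)) uv <- applyHomography(h, uv)
  hI <- nrow(image); wI <- ncol(image)
  px <- round(uv)
  keep <- px[, 1] >= 0 & px[, 1] <= wI - 1 & px[, 2] >= 0 & px[, 2] <= hI - 1
  mask <- matrix(FALSE, hI, wI)
  mask[cbind(px[keep, 2] + 1, px[keep, 1] + 1)] <- TRUE
  if (!is.null(pathPng)) {
    rgb <- array(rep(pmin(pmax(image, 0), 1), 3L), dim = c(hI, wI, 3L))
    rgb[, , 1][mask] <- 1
    rgb[, , 2][mask] <- 0.4 * rgb[, , 2][mask]
    rgb[, , 3][mask] <- 0.4 * rgb[, , 3][mask]
    png::writePNG(rgb, pathPng)
  }
  if (!is.null(pathPly)) writePly(faceCloudOptical, pathPly)
  invisible(list(mask = mask, pixels = uv))
}
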