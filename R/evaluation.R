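#' @include registration.R
NULL

#' Fiducial registration error of a registered face cloud
#'
#' Root-mean-square nearest-neighbour distance from the registered face cloud
#' (already transformed into the MR frame) to the MR face surface points.
#'
#' @param faceCloudInMr a [PointCloud-class] in the MR frame.
#' @param mrFace a [PointCloud-class] (surface sample) or [MRSurface-class]
#'   (distances to the triangulated surface are then used).
#' @return FRE in mm.
#' @export
computeFre <- function(faceCloudInMr, mrFace) {
  q <- if (is(faceCloudInMr, "PointCloud")) faceCloudInMr@points
       else asPointMatrix(faceCloudInMr)
  if (nrow(q) < 1L) stopf("empty face cloud")
  d <- if (is(mrFace, "MRSurface") && nrow(mrFace@triangles) > 0L)
    cpp_nn_mesh(q, mrFace@vertices, mrFace@triangles)$dist
  else {
    tp <- if (is(mrFace, "MRSurface")) mrFace@vertices
          else if (is(mrFace, "PointCloud")) mrFace@points else asPointMatrix(mrFace)
    cpp_nn_points(q, tp)$dist
  }
  sqrt(mean(d^2))
}

#' Target registration error via residual ICP
#'
#' The evaluation cloud (captured at a position not used for registration and
#' mapped into the MR frame through the registration-derived world pose) is
#' aligned to the MR surface by ICP; the TRE is the root-mean-square
#' displacement of the evaluation points under that residual correction.
#' `method = "nn"` instead reports the plain RMS nearest-neighbour distance.
#'
#' @param evalCloudInMr a [PointCloud-class] in the MR frame.
#' @param mrSurface an [MRSurface-class] (or [PointCloud-class]).
#' @param method `"icp"` (default) or `"nn"`.
#' @param cutoff ICP correspondence cutoff, mm.
#' @return TRE in mm.
#' @export
computeTre <- function(evalCloudInMr, mrSurface, method = c("icp", "nn"), cutoff = 50) {
  method <- match.arg(method)
  q <- if (is(evalCloudInMr, "PointCloud")) evalCloudInMr@points
       else asPointMatrix(evalCloudInMr)
  if (method == "nn") return(computeFre(q, mrSurface))
  src <- pointCloud(q, "eval")
  res <- icpRefine(src, mrSurface, identityTransform("eval"), cutoff = cutoff,
                   tol = 1e-7, maxIterations = 80L)
  moved <- transformPoints(res@T, q)
  sqrt(mean(rowSums((moved - q)^2)))
}

#' Relative registration error between two registrations
#'
#' Mean Euclidean distance between MR landmarks mapped by two independent
#' world poses of the same MR model.
#'
#' @param landmarksMr N x 3 matrix of landmark coordinates in the MR frame.
#' @param Ga,Gb [RigidTransform-class] world poses (world <- MR).
#' @return RRE in mm.
#' @export
computeRre <- function(landmarksMr, Ga, Gb) {
  X <- asPointMatrix(landmarksMr, "landmarksMr")
  pa <- transformPoints(rigidTransform(transformMatrix(Ga)), X)
  pb <- transformPoints(rigidTransform(transformMatrix(Gb)), X)
  mean(sqrt(rowSums((pa - pb)^2)))
}

#' Grid registration experiment on the phantom simulator
#'
#' Emulates the positioning-rig protocol: the camera is moved over a
#' `rows x cols` grid of positions (given spacing) in a plane facing the
#' phantom; at each position a depth capture is simulated and registered, and
#' the FRE is recorded. For the TRE, registration is performed at grid
#' positions and the camera is then moved to a separate evaluation position
#' whose capture, mapped through the registration-derived world pose, is
#' compared against the MR surface.
#'
#' @param scene a [simScene()] configuration.
#' @param grid `(rows, cols)` of the position grid (default `c(5, 5)`).
#' @param spacing grid spacing in mm (default 100).
#' @param nEvaluationTrials number of registration positions reused for TRE
#'   evaluation (default 5).
#' @param seed base RNG seed.
#' @param voxel depth-cloud downsampling voxel, mm.
#' @return List with `fre` and `tre` ([ErrorReport-class] objects), the
#'   per-position data frame `trials`, and `failures` (positions whose
#'   registration failed).
#' @export
runGridExperiment <- function(scene, grid = c(5, 5), spacing = 100,
                              nEvaluationTrials = 5, seed = 1L, voxel = 5) {
  mrFace <- extractMrFace(scene$surface)
  alignedMesh <- mrSurface(transformPoints(mrFace$alignment$transform,
                                           scene$surface@vertices),
                           scene$surface@triangles)
  offsets <- expand.grid(
    dx = (seq_len(grid[2]) - (grid[2] + 1) / 2) * spacing,
    dy = (seq_len(grid[1]) - (grid[1] + 1) / 2) * spacing)
  n <- nrow(offsets)
  fre <- rep(NA_real_, n); tre <- c(); Gerr <- rep(NA_real_, n)
  failures <- integer(0)
  Gs <- vector("list", n)
  for (k in seq_len(n)) {
    sk <- childSeed(seed, k)
    ok <- tryCatch({
      cap <- simulateCapture(scene, cameraOffset = c(offsets$dx[k], offsets$dy[k], 0),
                             seed = sk)
      cloud <- extractFaceCloud(cap$frame, cap$roi, scene$correction)
      small <- voxelDownsample(cloud, voxel)
      init <- tryCatch(
        ransacInitialTransform(small, mrFace$cloud, voxel = 8, seed = sk),
        error = function(e) pcaCoarseAlign(small, mrFace$cloud))
      init <- rigidTransform(transformMatrix(init), frameFrom = "optical",
                             frameTo = "virtual")
      res <- icpRefine(small, alignedMesh, init, tol = 1e-7, cutoff = 25,
                       maxIterations = 60L)
      Tmr <- compose(invert(mrFace$alignment$transform), res@T)
      G <- chainWorldPose(Tmr, cap$C, scene$M)
      moved <- transformPoints(res@T, small@points)
      fre[k] <- computeFre(moved, alignedMesh)
      Gs[[k]] <- G
      TRUE
    }, error = function(e) {
      warning(sprintf("grid position %d failed: %s", k, conditionMessage(e)))
      FALSE
    })
    if (!ok) failures <- c(failures, k)
  }
  # evaluation captures from a distinct (craniotomy-view) position
  nev <- min(nEvaluationTrials, sum(!is.na(fre)))
  okPos <- which(!is.na(fre))
  for (j in seq_len(nev)) {
    k <- okPos[j]
    sk <- childSeed(seed, 10000 + k)
    t <- tryCatch({
      cap <- simulateCapture(scene, cameraOffset = c(0, -150, -100), seed = sk,
                             evaluation = TRUE)
      cloud <- voxelDownsample(extractFaceCloud(cap$frame, cap$roi, scene$correction), voxel)
      # map the evaluation capture into the MR frame via the registration G
      worldPts <- transformPoints(rigidTransform(transformMatrix(compose(cap$C, scene$M))),
                                  cloud@points)
      mrPts <- transformPoints(invert(rigidTransform(transformMatrix(Gs[[k]]))), worldPts)
      computeTre(mrPts, scene$surface)
    }, error = function(e) NA_real_)
    tre <- c(tre, t)
  }
  trials <- data.frame(position = seq_len(n), dx = offsets$dx, dy = offsets$dy, fre = fre)
  list(fre = errorReport("FRE", fre[!is.na(fre)]),
       tre = errorReport("TRE", tre[!is.na(tre)]),
       trials = trials, failures = failures)
}
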