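#' @include depth.R mr.R
NULL

# Surface normals by local PCA over the k nearest neighbours, oriented to
# face the viewpoint (both clouds handled here are camera-facing surfaces).
localNormals <- function(pts, k = 10L, viewpoint = c(0, 0, 0)) {
  nn <- cpp_knn_points(pts, pts, as.integer(k + 1L))
  n <- nrow(pts)
  out <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    nb <- pts[nn$idx[i, ], , drop = FALSE]
    C <- crossprod(sweep(nb, 2, colMeans(nb)))
    out[i, ] <- eigen(C, symmetric = TRUE)$vectors[, 3]
  }
  flip <- rowSums(out * sweep(pts, 2, viewpoint)) > 0
  out[flip, ] <- -out[flip, ]
  out
}

# Fast point feature histograms (11 bins per Darboux angle, 33 dims): SPFH
# from the pair angle features (alpha, phi, theta), then neighbourhood
# re-weighting. Normals must be consistently oriented.
fpfhDescriptors <- function(pts, normals, radius) {
  n <- nrow(pts)
  nb <- 11L
  pairs <- cpp_radius_pairs(pts, radius)  # ordered (i, j) pairs, i != j
  spfh <- matrix(0, n, 3L * nb)
  if (nrow(pairs) > 0) {
    i <- pairs[, 1]; j <- pairs[, 2]
    dvec <- pts[j, , drop = FALSE] - pts[i, , drop = FALSE]
    dist <- sqrt(rowSums(dvec^2))
    dhat <- dvec / pmax(dist, 1e-12)
    ni <- normals[i, , drop = FALSE]; nj <- normals[j, , drop = FALSE]
    # Darboux frame at the source point: u = n_i, v = d x u, w = u x v
    v <- cbind(dhat[, 2] * ni[, 3] - dhat[, 3] * ni[, 2],
               dhat[, 3] * ni[, 1] - dhat[, 1] * ni[, 3],
               dhat[, 1] * ni[, 2] - dhat[, 2] * ni[, 1])
    v <- v / pmax(sqrt(rowSums(v^2)), 1e-12)
    w <- cbind(ni[, 2] * v[, 3] - ni[, 3] * v[, 2],
               ni[, 3] * v[, 1] - ni[, 1] * v[, 3],
               ni[, 1] * v[, 2] - ni[, 2] * v[, 1])
    alpha <- rowSums(v * nj)                       # [-1, 1]
    phi <- rowSums(ni * dhat)                      # [-1, 1]
    theta <- atan2(rowSums(w * nj), rowSums(ni * nj))  # [-pi, pi]
    binOf <- function(x, lo, hi) pmin(pmax(ceiling(nb * (x - lo) / (hi - lo)), 1L), nb)
    ba <- binOf(alpha, -1, 1); bp <- binOf(phi, -1, 1); bt <- binOf(theta, -pi, pi)
    for (b in seq_len(nb)) {
      spfh[, b] <- tabulate(i[ba == b], nbins = n)
      spfh[, nb + b] <- tabulate(i[bp == b], nbins = n)
      spfh[, 2L * nb + b] <- tabulate(i[bt == b], nbins = n)
    }
    rs <- rowSums(spfh[, 1:nb, drop = FALSE])
    spfh <- spfh / pmax(rs, 1)
    # FPFH: add the distance-weighted mean of the neighbours' SPFH
    wgt <- 1 / pmax(dist, 1e-6)
    su <- sort(unique(i))
    acc <- matrix(0, n, 3L * nb)
    acc[su, ] <- rowsum(spfh[j, , drop = FALSE] * wgt, i)
    wsum <- rep(0, n)
    wsum[su] <- rowsum(wgt, i)[, 1]
    fpfh <- spfh + acc / pmax(wsum, 1e-12)
  } else fpfh <- spfh
  fpfh / pmax(sqrt(rowSums(fpfh^2)), 1e-12)
}

#' RANSAC initial alignment between two point clouds
#'
#' Coarse global registration used to initialise ICP: both clouds are
#' voxel-downsampled, local normal-histogram shape descriptors are matched
#' across clouds, and triplets of matches are sampled; triplets passing an
#' edge-length compatibility test propose a rigid transform (Kabsch) which is
#' scored by its match inlier count under the distance threshold. Deterministic
#' for a fixed `seed`.
#'
#' @param source,target [PointCloud-class] objects (>= 3 points).
#' @param voxel downsampling voxel, mm (default 8).
#' @param inlierThreshold match distance below which a correspondence counts
#'   as an inlier, mm (default 10).
#' @param maxIterations RANSAC iteration cap (default 2000; stops earlier at
#'   0.999 confidence).
#' @param minInlierFraction minimum inlier fraction for success (default 0.15).
#' @param seed RNG seed (local to this call).
#' @return A [RigidTransform-class] mapping source coordinates into target
#'   coordinates, with attribute `"inlierFraction"`.
#' @export
ransacInitialTransform <- function(source, target, voxel = 8, inlierThreshold = 10,
                                   maxIterations = 2000L, minInlierFraction = 0.15,
                                   seed = 1L) {
  sp <- if (is(source, "PointCloud")) source@points else asPointMatrix(source)
  tp <- if (is(target, "PointCloud")) target@points else asPointMatrix(target)
  if (nrow(sp) < 3L || nrow(tp) < 3L)
    stopf("RANSAC initialisation needs at least 3 points in each cloud")
  sd <- voxelDownsample(sp, voxel); td <- voxelDownsample(tp, voxel)
  radius <- 5 * voxel
  sn <- localNormals(sd, k = 16L); tn <- localNormals(td, k = 16L)
  fs <- fpfhDescriptors(sd, sn, radius)
  ft <- fpfhDescriptors(td, tn, radius)
  # nearest descriptor (Euclidean) on the target for each source point
  cross <- -2 * (fs %*% t(ft))
  cross <- sweep(cross, 2L, rowSums(ft^2), "+")
  match <- max.col(-cross, ties.method = "first")
  n <- nrow(sd)
  withLocalSeed(seed, {
    # score hypotheses on a fixed subsample; refit the winner on all matches
    sc <- if (n > 300L) sort(sample.int(n, 300L)) else seq_len(n)
    sdS <- sd[sc, , drop = FALSE]; tdS <- td[match[sc], , drop = FALSE]
    best <- NULL; bestInl <- -1L
    iter <- 0L; needed <- maxIterations
    while (iter < min(maxIterations, needed)) {
      iter <- iter + 1L
      tri <- sample.int(n, 3L)
      A <- sd[tri, ]; B <- td[match[tri], ]
      dA <- c(dist(A)); dB <- c(dist(B))
      if (any(dA < voxel) || any(abs(dA - dB) > 2 * inlierThreshold)) next
      Tc <- tryCatch(kabschTransform(A, B), error = function(e) NULL)
      if (is.null(Tc)) next
      moved <- transformPoints(Tc, sdS)
      inl <- sum(sqrt(rowSums((moved - tdS)^2)) < inlierThreshold)
      if (inl > bestInl) {
        bestInl <- inl; best <- Tc
        w <- max(inl / nrow(sdS), 1e-6)
        needed <- ceiling(log(1 - 0.999) / log(1 - w^3))
      }
    }
    bestFrac <- max(bestInl, 0) / nrow(sdS)
    if (is.null(best) || bestFrac < minInlierFraction)
      stopf(paste("RANSAC initialisation failed (best inlier fraction %.2f);",
                  "consider a PCA-based coarse alignment as fallback"), bestFrac)
    for (polish in 1:3) {   # refit on the full inlier set until it stabilises
      moved <- transformPoints(best, sd)
      keep <- sqrt(rowSums((moved - td[match, , drop = FALSE])^2)) < inlierThreshold
      if (sum(keep) < 3L) break
      best <- kabschTransform(sd[keep, , drop = FALSE],
                              td[match[keep], , drop = FALSE])
    }
    out <- rigidTransform(transformMatrix(best),
                          frameFrom = if (is(source, "PointCloud")) source@frame else "a",
                          frameTo = if (is(target, "PointCloud")) target@frame else "b")
    attr(out, "inlierFraction") <- bestFrac
    out
  })
}

#' PCA-based coarse alignment of two camera-facing clouds
#'
#' Fallback initialiser when feature matching fails: aligns centroids and
#' principal axes of the two clouds, with axis signs fixed by projection
#' skewness (the same nose-ward heuristic the MR alignment uses) and the
#' third axis chosen right-handed. Suitable for face patches seen from
#' broadly similar directions.
#'
#' @param source,target [PointCloud-class] objects (or N x 3 matrices).
#' @return A [RigidTransform-class] mapping source onto target.
#' @export
pcaCoarseAlign <- function(source, target) {
  sp <- if (is(source, "PointCloud")) source@points else asPointMatrix(source)
  tp <- if (is(target, "PointCloud")) target@points else asPointMatrix(target)
  basis <- function(p) {
    ctr <- colMeans(p)
    X <- sweep(p, 2, ctr)
    ev <- eigen(crossprod(X) / nrow(X), symmetric = TRUE)
    e1 <- ev$vectors[, 1]; e2 <- ev$vectors[, 2]
    skew <- function(v) { t <- X %*% v; mean(t^3) / (mean(t^2)^1.5) }
    if (skew(e1) < 0) e1 <- -e1
    if (skew(e2) < 0) e2 <- -e2
    e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
            e1[3] * e2[1] - e1[1] * e2[3],
            e1[1] * e2[2] - e1[2] * e2[1])
    list(R = cbind(e1, e2, e3), ctr = ctr)
  }
  bs <- basis(sp); bt <- basis(tp)
  R <- bt$R %*% t(bs$R)
  rigidTransform(R, bt$ctr - R %*% bs$ctr,
                 frameFrom = if (is(source, "PointCloud")) source@frame else "a",
                 frameTo = if (is(target, "PointCloud")) target@frame else "b")
}

# One point-to-plane Gauss-Newton step given foot points and normals.
pointToPlaneStep <- function(src, foot, normals) {
  r <- rowSums((src - foot) * normals)
  J <- cbind(
    src[, 2] * normals[, 3] - src[, 3] * normals[, 2],
    src[, 3] * normals[, 1] - src[, 1] * normals[, 3],
    src[, 1] * normals[, 2] - src[, 2] * normals[, 1],
    normals)
  x <- tryCatch(solve(crossprod(J), -crossprod(J, r)), error = function(e) rep(0, 6))
  rigidTransform(rotationVectorToMatrix(x[1:3]), x[4:6])
}

#' Refine a registration with the iterative closest point algorithm
#'
#' Point-to-point ICP with trimmed correspondences: at each iteration the
#' transformed source points are matched to their nearest neighbours on the
#' target (a point cloud, or a triangle mesh via closest point on surface),
#' matches beyond `cutoff` are discarded, and the pose is updated by a Kabsch
#' fit (or a point-to-plane Gauss-Newton step when `variant = "point-to-plane"`,
#' available for mesh targets). Iterations stop when the relative change of
#' the inlier RMSE falls below `tol`.
#'
#' @param source a [PointCloud-class].
#' @param target a [PointCloud-class] or an [MRSurface-class] with triangles.
#' @param init initial [RigidTransform-class] (source frame -> target frame).
#' @param maxIterations iteration cap (default 100).
#' @param tol relative RMSE-change convergence tolerance (default 1e-6).
#' @param cutoff correspondence distance cutoff, mm (default 25).
#' @param variant `"point-to-point"` (default) or `"point-to-plane"`.
#' @return A [RegistrationResult-class]; its `T` maps source coordinates into
#'   the target frame.
#' @export
icpRefine <- function(source, target, init, maxIterations = 100L, tol = 1e-6,
                      cutoff = 25, variant = c("point-to-point", "point-to-plane")) {
  variant <- match.arg(variant)
  sp <- if (is(source, "PointCloud")) source@points else asPointMatrix(source)
  meshTarget <- is(target, "MRSurface") && nrow(target@triangles) > 0L
  tp <- if (is(target, "MRSurface")) target@vertices
        else if (is(target, "PointCloud")) target@points else asPointMatrix(target)
  if (variant == "point-to-plane" && !meshTarget)
    stopf("point-to-plane ICP requires a triangle-mesh target")
  Tm <- transformMatrix(init)
  correspond <- function(Tm) {
    cur <- sweep(sp %*% t(Tm[1:3, 1:3]), 2L, -Tm[1:3, 4], "-")
    if (meshTarget) {
      nnr <- cpp_nn_mesh(cur, tp, target@triangles)
      list(cur = cur, foot = nnr$foot, d = nnr$dist, face = nnr$face)
    } else {
      nnr <- cpp_nn_points(cur, tp)
      list(cur = cur, foot = tp[nnr$idx, , drop = FALSE], d = nnr$dist)
    }
  }
  rmse <- Inf; converged <- FALSE; iter <- 0L
  repeat {
    iter <- iter + 1L
    cr <- correspond(Tm)
    keep <- cr$d <= cutoff
    if (sum(keep) < 3L)
      stopf("correspondence starvation: fewer than 3 matches within the %g mm cutoff", cutoff)
    newRmse <- sqrt(mean(cr$d[keep]^2))
    if ((is.finite(rmse) && abs(rmse - newRmse) <= tol * max(rmse, 1e-12)) ||
        newRmse < 1e-12) {
      rmse <- newRmse; converged <- TRUE; break
    }
    rmse <- newRmse
    if (variant == "point-to-point") {
      upd <- kabschTransform(cr$cur[keep, , drop = FALSE], cr$foot[keep, , drop = FALSE])
    } else {
      tri <- target@triangles[cr$face[keep], , drop = FALSE]
      e1 <- tp[tri[, 2], ] - tp[tri[, 1], ]
      e2 <- tp[tri[, 3], ] - tp[tri[, 1], ]
      nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                   e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                   e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
      nrm <- nrm / pmax(sqrt(rowSums(nrm^2)), 1e-12)
      upd <- pointToPlaneStep(cr$cur[keep, , drop = FALSE],
                              cr$foot[keep, , drop = FALSE], nrm)
    }
    Tm <- transformMatrix(upd) %*% Tm
    if (iter >= maxIterations) {
      # report the RMSE of the final pose even when stopping on the cap
      cr <- correspond(Tm)
      keep <- cr$d <= cutoff
      rmse <- sqrt(mean(cr$d[keep]^2))
      break
    }
  }
  Tfin <- rigidTransform(Tm,
                         frameFrom = if (is(source, "PointCloud")) source@frame else frameFrom(init),
                         frameTo = frameTo(init))
  new("RegistrationResult", T = Tfin, icpRmse = rmse, nIterations = iter,
      converged = converged, inlierFraction = NA_real_)
}

#' Chain the per-frame registration into the tracker world
#'
#' `G = C M T^-1`: with `T` (MR <- optical) the frame registration, `M`
#' (body <- optical) the rig calibration and `C` (world <- body) the tracked
#' camera pose, `G` is the absolute pose of the MR model in tracker world.
#'
#' @param T [RigidTransform-class], MR <- optical.
#' @param C [RigidTransform-class], tracker world <- camera body.
#' @param M [RigidTransform-class], camera body <- optical.
#' @return `G` as a [RigidTransform-class] (tracker world <- MR).
#' @export
chainWorldPose <- function(T, C, M) compose(C, compose(M, invert(T)))

#' Register a stream of depth-frame clouds against the MR face
#'
#' Runs the per-frame registration loop: RANSAC initialisation on the first
#' frame, ICP refinement warm-started from the previous frame's transform
#' thereafter, chaining into world poses through the tracked camera pose and
#' the rig calibration, and Kalman filtering of the world pose stream.
#'
#' @param frames list; each element a list with `cloud` (a
#'   [PointCloud-class] in the IR optical frame) and `C` (the tracked
#'   [RigidTransform-class], world <- body).
#' @param mrFace result of [extractMrFace()] (preferred: its alignment is used
#'   to express `T` in the MR frame), or a [PointCloud-class] already in the
#'   MR frame.
#' @param M rig calibration (body <- optical), e.g. from [calibrateTracking()].
#' @param targetMesh optional [MRSurface-class] in the MR frame (when
#'   `mrFace` is an [extractMrFace()] result, it is moved into the virtual
#'   camera frame automatically); when supplied, ICP matches against the
#'   mesh surface instead of the face point sample.
#' @param downsample `"centroid"` (noise-smoothing) or `"sample"`
#'   (surface-preserving) voxel downsampling of the depth clouds.
#' @param variant ICP variant, see [icpRefine()].
#' @param voxel downsampling voxel for the depth clouds, mm.
#' @param cutoff,icpTol,icpMaxIterations ICP parameters.
#' @param ransacSeed seed for the first-frame initialisation.
#' @param filter a [PoseFilterState-class] from [poseFilter()], or NULL for
#'   the default filter.
#' @return List with `results` (per-frame [RegistrationResult-class]), `G`
#'   (per-frame raw world poses), `filteredG` (per-frame filtered world
#'   poses), `failed` (indices of skipped frames).
#' @export
registerStream <- function(frames, mrFace, M, targetMesh = NULL,
                           variant = "point-to-point", voxel = 4,
                           downsample = "centroid",
                           cutoff = 25, icpTol = 1e-9, icpMaxIterations = 200L,
                           ransacSeed = 1L, filter = NULL) {
  if (length(frames) == 0L) stopf("no frames to register")
  haveAlign <- is.list(mrFace) && !is.null(mrFace$alignment)
  faceCloud <- if (haveAlign) mrFace$cloud else mrFace
  toMr <- if (haveAlign) invert(mrFace$alignment$transform) else NULL
  target <- if (!is.null(targetMesh)) {
    if (haveAlign)
      mrSurface(transformPoints(mrFace$alignment$transform, targetMesh@vertices),
                targetMesh@triangles, provenance = targetMesh@provenance)
    else targetMesh
  } else faceCloud
  if (is.null(filter)) filter <- poseFilter()
  results <- vector("list", length(frames))
  Gs <- vector("list", length(frames))
  Gf <- vector("list", length(frames))
  failed <- integer(0)
  prevT <- NULL
  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    res <- tryCatch({
      cloud <- fr$cloud
      small <- voxelDownsample(cloud, voxel, method = downsample)
      init <- if (is.null(prevT)) {
        rt <- tryCatch(
          ransacInitialTransform(small, faceCloud, voxel = max(voxel, 8),
                                 seed = ransacSeed),
          error = function(e) pcaCoarseAlign(small, faceCloud))
        rigidTransform(transformMatrix(rt), frameFrom = "optical",
                       frameTo = cloudFrame(faceCloud))
      } else prevT
      r <- icpRefine(small, target, init, maxIterations = icpMaxIterations,
                     tol = icpTol, cutoff = cutoff, variant = variant)
      r
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("frame %d registration failed: %s", i, conditionMessage(res)))
      failed <- c(failed, i)
      next
    }
    prevT <- res@T
    Tmr <- if (haveAlign) compose(toMr, res@T) else res@T
    G <- chainWorldPose(Tmr, fr$C, M)
    filter <- kalmanUpdate(filter, G,
                           measurementNoise = c(max(res@icpRmse^2, 1e-8), NA))
    res@T <- Tmr   # the reported per-frame transform is MR <- optical
    results[[i]] <- res
    Gs[[i]] <- G
    Gf[[i]] <- filteredPose(filter, frameFrom = frameFrom(G), frameTo = frameTo(G))
  }
  if (length(failed) > length(frames) / 2)
    stopf("stream registration failed on %d of %d frames", length(failed), length(frames))
  list(results = results, G = Gs, filteredG = Gf, failed = failed)
}
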