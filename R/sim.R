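#' @include evaluation.R kalman.R
NULL

#' Noise configuration for the phantom simulator
#'
#' Defaults emulate the published characterisation of the simulated hardware:
#' a smooth distance-dependent systematic depth bias of roughly 11 mm at the
#' 600 mm working distance, sub-millimetre tracker noise (0.34 mm RMS), and
#' 0.5 px marker-centroid noise. The single-pixel random depth error of such
#' time-of-flight sensors is characterised at up to ~17 mm standard
#' deviation; the default effective per-pixel value here is 2 mm,
#' representing the spatial/temporal averaging any consumer of the raw
#' stream applies, with the worst case available for stress tests.
#'
#' @param depthBias ascending polynomial coefficients of the systematic bias
#'   added to the true depth (mm): `raw = true + b0 + b1 true + b2 true^2`.
#'   The default `c(5, 0.01)` gives 11 mm at 600 mm.
#' @param depthRandomSd per-pixel Gaussian depth noise, mm.
#' @param trackerRms tracker pose noise (translation RMS, mm); rotational
#'   noise is scaled as `trackerRms / 500` rad (the RMS over a ~0.5 m lever).
#' @param pixelNoiseSd marker-centroid jitter in the IR image, px.
#' @return Named list of class `"noiseConfig"`.
#' @export
noiseConfig <- function(depthBias = c(5, 0.01), depthRandomSd = 2,
                        trackerRms = 0.34, pixelNoiseSd = 0.5) {
  stopifnot(depthRandomSd >= 0, trackerRms >= 0, pixelNoiseSd >= 0)
  structure(list(depthBias = as.numeric(depthBias),
                 depthRandomSd = depthRandomSd,
                 trackerRms = trackerRms,
                 pixelNoiseSd = pixelNoiseSd), class = "noiseConfig")
}

#' Zero-noise configuration (for closed-loop tests)
#' @return A `noiseConfig` with every noise source and the depth bias at zero.
#' @export
noiselessConfig <- function()
  noiseConfig(depthBias = c(0, 0), depthRandomSd = 0, trackerRms = 0, pixelNoiseSd = 0)

unitVector <- function(v) v / sqrt(sum(v^2))

# Smooth angular bump used to sculpt the head surface.
angularBump <- function(dirs, centre, amplitude, width) {
  ang <- acos(pmin(pmax(as.numeric(dirs %*% unitVector(centre)), -1), 1))
  amplitude * exp(-0.5 * (ang / width)^2)
}

#' Generate a parametric phantom head
#'
#' Watertight triangle mesh of a head-like surface: an anisotropic ellipsoid
#' cranium (semi-axes 70 x 100 x 80 mm: left-right, vertical, back-front)
#' with a prominent nose protrusion on the `+z` side, brow and chin
#' asperities for asymmetry, and a few small seeded bumps so that two seeds
#' give distinct but reproducible phantoms. The vertical axis dominates the
#' covariance (first principal component) and the nose fixes the sign of the
#' second, as the face-alignment step expects.
#'
#' @param seed RNG seed for the small random asperities.
#' @param semiAxes ellipsoid semi-axes `(x, y, z)` in mm.
#' @param noseAmplitude nose protrusion height, mm (0 disables it).
#' @param resolution polar x azimuthal vertex resolution.
#' @return List with `surface` (an [MRSurface-class], MR frame, centroid near
#'   the origin) and `landmarks` (3 x 3 matrix: nose tip and two canthus-like
#'   points, rows named).
#' @export
generateHead <- function(seed = 1L, semiAxes = c(70, 100, 80), noseAmplitude = 25,
                         resolution = c(48L, 64L)) {
  if (max(semiAxes) / min(semiAxes) < 1.05 && noseAmplitude == 0)
    warning("near-isotropic head parameters: PCA alignment will be ambiguous by design")
  nT <- resolution[1]; nP <- resolution[2]
  theta <- seq(0, pi, length.out = nT + 1L)[2:nT]          # interior rings
  phi <- seq(0, 2 * pi, length.out = nP + 1L)[seq_len(nP)] # no duplicate seam
  grid <- expand.grid(phi = phi, theta = theta)
  dirs <- cbind(sin(grid$theta) * cos(grid$phi),
                cos(grid$theta),
                sin(grid$theta) * sin(grid$phi))
  dirs <- rbind(c(0, 1, 0), dirs, c(0, -1, 0))             # poles first/last
  # base ellipsoid radius along each direction
  r <- 1 / sqrt(rowSums(sweep(dirs, 2L, semiAxes, "/")^2))
  # facial features (directions in the MR frame: +y crown, +z face)
  bump <- angularBump(dirs, c(0, -0.15, 1), noseAmplitude, 0.16) +   # nose
          angularBump(dirs, c(0, 0.40, 1), 6, 0.35) +                # brow
          angularBump(dirs, c(0, -0.80, 0.55), 10, 0.30)             # chin
  bump <- bump + withLocalSeed(seed, {
    nb <- 4L
    centres <- matrix(rnorm(3 * nb), nb, 3)
    amps <- runif(nb, 1, 3); widths <- runif(nb, 0.25, 0.5)
    rowSums(vapply(seq_len(nb), function(b)
      angularBump(dirs, centres[b, ], amps[b], widths[b]), numeric(nrow(dirs))))
  })
  V <- dirs * (r + bump)
  # triangles: pole fans + quad strips between rings
  idx <- function(i, j) 1L + (i - 1L) * nP + ((j - 1L) %% nP) + 1L  # ring i, seg j
  F <- list()
  for (j in seq_len(nP)) F[[length(F) + 1L]] <- c(1L, idx(1L, j + 1L), idx(1L, j))
  nR <- nT - 1L
  for (i in seq_len(nR - 1L)) for (j in seq_len(nP)) {
    a <- idx(i, j); b <- idx(i, j + 1L); cc <- idx(i + 1L, j); d <- idx(i + 1L, j + 1L)
    F[[length(F) + 1L]] <- c(a, b, d)
    F[[length(F) + 1L]] <- c(a, d, cc)
  }
  last <- nrow(V)
  for (j in seq_len(nP)) F[[length(F) + 1L]] <- c(last, idx(nR, j), idx(nR, j + 1L))
  Fm <- do.call(rbind, F)
  V <- sweep(V, 2L, colMeans(V))   # centre the MR frame on the centroid
  landmarkAt <- function(dir) V[which.max(V %*% unitVector(dir)), ]
  lm <- rbind(noseTip = landmarkAt(c(0, -0.15, 1)),
              rightCanthus = landmarkAt(c(0.5, 0.1, 0.85)),
              leftCanthus = landmarkAt(c(-0.5, 0.1, 0.85)))
  list(surface = mrSurface(V, Fm, provenance = "synthetic"), landmarks = lm)
}

# Look-at pose: optical frame at `eye`, +z toward `at`, up vector (world) `up`.
lookAtPose <- function(eye, at, up = c(0, 1, 0), frameFrom = "optical", frameTo = "world") {
  z <- unitVector(at - eye)
  yc <- -unitVector(up)                       # +y is down in the image
  yc <- unitVector(yc - sum(yc * z) * z)
  xc <- c(yc[2] * z[3] - yc[3] * z[2], yc[3] * z[1] - yc[1] * z[3], yc[1] * z[2] - yc[2] * z[1])
  rigidTransform(cbind(xc, yc, z), eye, frameFrom, frameTo)
}

#' Build a simulated acquisition scene
#'
#' Assembles the full synthetic rig: phantom head, its pose in tracker world,
#' the IR camera, the ground-truth body-to-optical calibration `M`, the base
#' camera standoff, the noise configuration, and a depth correction fitted on
#' a noiseless plane sweep of the scene's own bias curve.
#'
#' @param seed scene seed (head shape and pose).
#' @param noise a [noiseConfig()].
#' @param camera the IR [CameraModel-class].
#' @param viewDistance camera standoff from the face, mm.
#' @param fitCorrection fit the depth correction at build time (default TRUE;
#'   set FALSE to use the identity, e.g. to expose the raw bias).
#' @return A list of class `"simScene"` with components `head`, `surface`,
#'   `landmarks`, `headPose` (world <- MR), `camera`, `M` (body <- optical),
#'   `baseOptical` (world <- optical), `noise`, `correction`, `seed`.
#' @export
simScene <- function(seed = 1L, noise = noiseConfig(), camera = irCameraDefault(),
                     viewDistance = 600, fitCorrection = TRUE) {
  head <- generateHead(seed)
  headPose <- withLocalSeed(childSeed(seed, 1L), {
    rigidTransform(rotationVectorToMatrix(runif(3, -0.15, 0.15)),
                   c(runif(2, -50, 50), runif(1, -30, 30)),
                   frameFrom = "MR", frameTo = "tracker")
  })
  # ground-truth rig calibration: optical centre offset from the marker body
  M <- rigidTransform(rotationVectorToMatrix(c(0.06, -0.1, 0.04)), c(30, 20, 50),
                      frameFrom = "optical", frameTo = "body")
  noseWorld <- transformMatrix(headPose)[1:3, 1:3] %*% c(0, -0.15, 1)
  upWorld <- transformMatrix(headPose)[1:3, 1:3] %*% c(0, 1, 0)
  centreWorld <- transformMatrix(headPose)[1:3, 4]
  eye <- as.numeric(centreWorld + viewDistance * unitVector(noseWorld))
  baseOptical <- lookAtPose(eye, as.numeric(centreWorld), as.numeric(upWorld),
                            frameFrom = "optical", frameTo = "tracker")
  # the tracker world is set up (as a physical rig would be) so that its +x
  # axis runs against the image u axis: the linear-tool ordering convention
  # (highest tracker x <-> lowest u) is then satisfiable
  if (transformMatrix(baseOptical)[1, 1] > 0) {
    flip <- rigidTransform(diag(c(-1, -1, 1)), c(0, 0, 0),
                           frameFrom = "tracker", frameTo = "tracker")
    headPose <- compose(flip, headPose)
    baseOptical <- compose(flip, baseOptical)
  }
  scene <- list(head = head, surface = head$surface, landmarks = head$landmarks,
                headPose = headPose, camera = camera, M = M,
                baseOptical = baseOptical, noise = noise,
                correction = identityDepthCorrection(c(100, 2000)), seed = seed)
  class(scene) <- "simScene"
  if (fitCorrection && any(noise$depthBias != 0)) {
    sw <- simulatePlaneSweep(scene, reps = 1L, noiseless = TRUE)
    scene$correction <- fitDepthCorrection(sw)
  }
  scene
}

# Perturb a pose by tracker noise (translation RMS in mm, small rotation).
perturbPose <- function(pose, trackerRms) {
  if (trackerRms == 0) return(pose)
  dt <- rnorm(3, 0, trackerRms / sqrt(3))
  dr <- rnorm(3, 0, trackerRms / 500 / sqrt(3))
  rigidTransform(rotationVectorToMatrix(dr) %*% transformMatrix(pose)[1:3, 1:3],
                 transformMatrix(pose)[1:3, 4] + dt,
                 frameFrom(pose), frameTo(pose))
}

#' Render a depth frame of the scene
#'
#' Transforms the head mesh into the optical frame of the (possibly offset)
#' camera, rasterises it into a z-buffer at the IR resolution, adds the
#' systematic distance-dependent bias and per-pixel Gaussian noise of the
#' noise configuration, and returns the frame together with the oracle face
#' bounding box (projected head extent) and the tracked camera-body pose.
#'
#' @param scene a [simScene()].
#' @param cameraOffset world-frame displacement of the camera from its base
#'   position, mm (the camera is re-aimed at the head centre).
#' @param seed RNG seed for the noise draws.
#' @param noiseless overrides the scene noise with zero noise.
#' @param mesh optional [MRSurface-class] override in the MR frame (e.g. a
#'   plane target).
#' @return List: `frame` ([DepthFrame-class], raw biased depths), `roi`
#'   (oracle [FaceROI-class]), `C` (tracked pose, with tracker noise),
#'   `Ctrue`, `optical` (true world <- optical pose).
#' @export
renderDepth <- function(scene, cameraOffset = c(0, 0, 0), seed = 1L,
                        noiseless = FALSE, mesh = NULL) {
  noise <- if (noiseless) noiselessConfig() else scene$noise
  centreWorld <- transformMatrix(scene$headPose)[1:3, 4]
  eye0 <- transformMatrix(scene$baseOptical)[1:3, 4]
  up <- transformMatrix(scene$headPose)[1:3, 1:3] %*% c(0, 1, 0)
  optical <- lookAtPose(as.numeric(eye0 + cameraOffset), as.numeric(centreWorld),
                        as.numeric(up), frameFrom = "optical", frameTo = "tracker")
  surf <- if (is.null(mesh)) scene$surface else mesh
  Vw <- transformPoints(rigidTransform(transformMatrix(scene$headPose)), surf@vertices)
  Vo <- transformPoints(invert(rigidTransform(transformMatrix(optical))), Vw)
  if (all(Vo[, 3] <= 0)) stopf("empty frame: target entirely behind the camera")
  keepV <- Vo[, 3] > 1
  cam <- scene$camera
  uvz <- matrix(0, nrow(Vo), 3)
  uvz[keepV, 1:2] <- projectPoints(cam, Vo[keepV, , drop = FALSE])
  uvz[, 3] <- Vo[, 3]
  uvz[!keepV, 3] <- -1
  depth <- cpp_rasterize_zbuffer(uvz[, 1], uvz[, 2], uvz[, 3], surf@triangles,
                                 cam@width, cam@height)
  if (!any(depth > 0)) stopf("empty frame: target outside the camera frustum")
  valid <- depth > 0
  true <- depth[valid]
  raw <- true + polyEval(noise$depthBias, true)
  withLocalSeed(seed, {
    if (noise$depthRandomSd > 0) raw <- raw + rnorm(length(raw), 0, noise$depthRandomSd)
    depth[valid] <- pmax(raw, 0)
    Cpose <- compose(optical, invert(scene$M))   # world <- body
    Cnoisy <- perturbPose(Cpose, noise$trackerRms)
    vi <- which(valid, arr.ind = TRUE)
    pad <- 2
    roi <- faceROI(c(max(min(vi[, 2]) - 1 - pad, 0), max(min(vi[, 1]) - 1 - pad, 0),
                     min(max(vi[, 2]) - 1 + pad, cam@width - 1),
                     min(max(vi[, 1]) - 1 + pad, cam@height - 1)), source = "oracle")
    list(frame = depthFrame(depth, cam, timestamp = as.numeric(seed)),
         roi = roi, C = Cnoisy, Ctrue = Cpose, optical = optical)
  })
}

#' @rdname renderDepth
#' @param evaluation unused flag reserved for protocol bookkeeping.
#' @export
simulateCapture <- function(scene, cameraOffset = c(0, 0, 0), seed = 1L,
                            evaluation = FALSE) {
  renderDepth(scene, cameraOffset, seed)
}

#' Simulate the plane-sweep depth-calibration protocol
#'
#' Emulates measuring a fronto-parallel white plane at a series of stations:
#' at each station and repetition, a patch of depth pixels receives the
#' scene's systematic bias and per-pixel noise, and the patch mean is one raw
#' measurement paired with the tracker-measured true distance.
#'
#' @param scene a [simScene()].
#' @param stations true distances, mm (default 17 stations at 5 cm spacing
#'   spanning an 80 cm range).
#' @param reps repetitions per station (default 25).
#' @param patch side of the averaged pixel patch (default 21).
#' @param seed RNG seed.
#' @param noiseless disable the random component (bias only).
#' @return Data frame with columns `true` and `raw` (mm), one row per
#'   station x repetition.
#' @export
simulatePlaneSweep <- function(scene, stations = seq(250, 1050, by = 50), reps = 25L,
                               patch = 21L, seed = 1L, noiseless = FALSE) {
  noise <- scene$noise
  sdpx <- if (noiseless) 0 else noise$depthRandomSd
  withLocalSeed(seed, {
    rows <- lapply(stations, function(s) {
      raw <- s + polyEval(noise$depthBias, s) +
        if (sdpx > 0) rnorm(reps, 0, sdpx / patch) else 0
      data.frame(true = rep(s, reps), raw = raw)
    })
    do.call(rbind, rows)
  })
}

# Saturated marker blob: a Gaussian point-spread profile whose core clips at
# the sensor ceiling. The smooth skirt makes the discrete intensity-weighted
# centroid match the true centre to numerical precision.
stampMarker <- function(img, u, v, radius) {
  sigma <- radius / 1.4   # saturated core then always covers >= 4 pixel centres
  ext <- ceiling(8 * sigma)
  h <- nrow(img); w <- ncol(img)
  c0 <- max(floor(u - ext), 0); c1 <- min(ceiling(u + ext), w - 1)
  r0 <- max(floor(v - ext), 0); r1 <- min(ceiling(v + ext), h - 1)
  if (c0 > c1 || r0 > r1) return(img)
  cs <- c0:c1; rs <- r0:r1
  d2 <- outer((rs - v)^2, (cs - u)^2, "+")
  g <- exp(-d2 / (2 * sigma^2))
  val <- g * (2 - g)   # saturating PSF; polynomial in a Gaussian, so the
                       # sampled intensity-weighted centroid is exact
  img[rs + 1, cs + 1] <- pmax(img[rs + 1, cs + 1], val)
  img
}

#' Render a calibration capture of the tracked linear marker tool
#'
#' Projects the tool's reflective markers into the IR camera and stamps
#' anti-aliased saturated disks at the (noise-jittered) projections; tracker
#' noise perturbs both the reported camera-body pose and the reported marker
#' positions. Ground truth is attached as attributes.
#'
#' @param scene a [simScene()].
#' @param toolPose [RigidTransform-class] (tool <- world is its inverse; this
#'   is world <- tool) placing the tool in tracker world.
#' @param markerSpacing spacing of the collinear markers along the tool x
#'   axis, mm.
#' @param nMarkers number of markers on the tool.
#' @param markerRadius rendered blob radius, px.
#' @param cameraOffset camera displacement as in [renderDepth()].
#' @param seed RNG seed.
#' @param noiseless disable all noise.
#' @return A [CalibrationCapture-class]; attributes `Vtrue` (world <-
#'   optical) and `Ctrue`.
#' @export
renderCalibrationCapture <- function(scene, toolPose, markerSpacing = 40,
                                     nMarkers = 4L, markerRadius = 3,
                                     cameraOffset = c(0, 0, 0), seed = 1L,
                                     noiseless = FALSE) {
  noise <- if (noiseless) noiselessConfig() else scene$noise
  centreWorld <- transformMatrix(scene$headPose)[1:3, 4]
  eye0 <- transformMatrix(scene$baseOptical)[1:3, 4]
  up <- transformMatrix(scene$headPose)[1:3, 1:3] %*% c(0, 1, 0)
  optical <- lookAtPose(as.numeric(eye0 + cameraOffset), as.numeric(centreWorld),
                        as.numeric(up), frameFrom = "optical", frameTo = "tracker")
  local <- cbind((seq_len(nMarkers) - 1) * markerSpacing, 0, 0)
  Xw <- transformPoints(rigidTransform(transformMatrix(toolPose)), local)
  Xo <- transformPoints(invert(rigidTransform(transformMatrix(optical))), Xw)
  if (any(Xo[, 3] <= 10)) stopf("markers behind or too close to the camera; capture skipped")
  cam <- scene$camera
  uv <- projectPoints(cam, Xo)
  inside <- uv[, 1] >= 2 & uv[, 1] <= cam@width - 3 & uv[, 2] >= 2 & uv[, 2] <= cam@height - 3
  if (!all(inside)) stopf("markers outside the camera frustum; capture skipped")
  # the linear-tool ordering convention must hold for the capture to be usable:
  # descending tracker x along the tool pairs with ascending image u
  if (!identical(order(Xw[, 1], decreasing = TRUE), order(uv[, 1])) ||
      min(diff(sort(Xw[, 1]))) < 1 || min(diff(sort(uv[, 1]))) < 3)
    stopf("tool orientation violates the x/u ordering convention; capture skipped")
  if (min(dist(uv)) < 8 * markerRadius)
    stopf("markers project too close together (blobs would interact); capture skipped")
  withLocalSeed(seed, {
    if (noise$pixelNoiseSd > 0)
      uv <- uv + matrix(rnorm(length(uv), 0, noise$pixelNoiseSd), ncol = 2)
    img <- matrix(0, cam@height, cam@width)
    for (i in seq_len(nrow(uv))) img <- stampMarker(img, uv[i, 1], uv[i, 2], markerRadius)
    Cpose <- compose(optical, invert(scene$M))
    Cnoisy <- perturbPose(Cpose, noise$trackerRms)
    Xrep <- Xw + if (noise$trackerRms > 0)
      matrix(rnorm(length(Xw), 0, noise$trackerRms / sqrt(3)), ncol = 3) else 0
    cap <- new("CalibrationCapture", irImage = img, cameraBodyPose = Cnoisy,
               toolMarkerPositions = Xrep)
    attr(cap, "Vtrue") <- optical
    attr(cap, "Ctrue") <- Cpose
    cap
  })
}

#' Simulate a set of tracking-calibration captures
#'
#' Places the linear tool at a sequence of positions and orientations in
#' front of the camera (translations spread in all three axes and rotations
#' about varying axes, so the pooled marker set is non-coplanar) and renders
#' one capture per pose.
#'
#' @param scene a [simScene()].
#' @param n number of captures (default 20).
#' @param seed RNG seed.
#' @param noiseless disable all noise.
#' @return List of [CalibrationCapture-class] objects.
#' @export
simulateTrackingCaptures <- function(scene, n = 20L, seed = 1L, noiseless = FALSE) {
  optical <- scene$baseOptical
  Rw <- transformMatrix(optical)[1:3, 1:3]
  eye <- transformMatrix(optical)[1:3, 4]
  caps <- vector("list", n)
  k <- 0L; attempt <- 0L
  while (k < n) {
    attempt <- attempt + 1L
    if (attempt > 60L * n) stopf("could not place %d valid tool poses", n)
    cap <- withLocalSeed(childSeed(seed, attempt), {
      # tool centre in the frustum at varying depth/offsets; orientation
      # sampled and re-rendered until the x/u ordering convention holds
      centreOpt <- c(runif(1, -90, 90), runif(1, -70, 70), runif(1, 420, 640))
      centreW <- as.numeric(Rw %*% centreOpt + eye)
      Rtool <- rotationVectorToMatrix(rnorm(3, 0, 0.9))
      toolPose <- rigidTransform(Rtool, centreW - Rtool %*% c(60, 0, 0),
                                 frameFrom = "tool", frameTo = "tracker")
      tryCatch(renderCalibrationCapture(scene, toolPose,
                                        seed = childSeed(seed, 10000L + attempt),
                                        noiseless = noiseless),
               error = function(e) NULL)
    })
    if (!is.null(cap)) { k <- k + 1L; caps[[k]] <- cap }
  }
  caps
}

#' Simulate chessboard-corner shots for homography calibration
#'
#' Generates corner correspondences as seen by the infrared, RGB and
#' hyperspectral cameras of the rig after interpolation to the common 4K
#' resolution: a ground-truth projective homography per camera pair (a mild
#' perspective distortion of a similarity, emulating the nearly coincident
#' rig cameras) maps the infrared corner grid of each shot, and centroid
#' noise is added to every corner.
#'
#' @param seed RNG seed.
#' @param nShots number of board placements (default 8).
#' @param gridRows,gridCols corner grid shape (default 25 x 32).
#' @param noiseSd corner noise at 4K, px.
#' @return List with `corners` (data frame: camera, shot, row, col, u, v) and
#'   `truth` (named list of 3x3 ground-truth homographies `IR:RGB`, `IR:HS`).
#' @export
simulateHomographyShots <- function(seed = 1L, nShots = 8L, gridRows = 25L,
                                    gridCols = 32L, noiseSd = 0.5) {
  withLocalSeed(seed, {
    size <- c(3840, 2160)
    randomH <- function() {
      ang <- runif(1, -0.06, 0.06); s <- runif(1, 0.92, 1.08)
      A <- s * matrix(c(cos(ang), -sin(ang), sin(ang), cos(ang)), 2, 2, byrow = TRUE)
      H <- rbind(cbind(A, runif(2, -80, 80)),
                 c(runif(2, -2e-5, 2e-5), 1))
      H
    }
    truth <- list("IR:RGB" = randomH(), "IR:HS" = randomH())
    rows <- list()
    for (shot in seq_len(nShots)) {
      # board corners spread over the IR view, with a random similarity jitter
      u0 <- runif(1, 300, 900); v0 <- runif(1, 200, 500)
      du <- runif(1, 70, 95); dv <- runif(1, 55, 70)
      ang <- runif(1, -0.15, 0.15)
      g <- expand.grid(col = seq_len(gridCols), row = seq_len(gridRows))
      u <- u0 + (g$col - 1) * du * cos(ang) - (g$row - 1) * dv * sin(ang)
      v <- v0 + (g$col - 1) * du * sin(ang) + (g$row - 1) * dv * cos(ang)
      ir <- cbind(u, v)
      for (camera in c("IR", "RGB", "HS")) {
        uv <- switch(camera, IR = ir,
                     RGB = applyHomography(truth[["IR:RGB"]], ir),
                     HS = applyHomography(truth[["IR:HS"]], ir))
        uv <- uv + matrix(rnorm(length(uv), 0, noiseSd), ncol = 2)
        rows[[length(rows) + 1L]] <- data.frame(
          camera = camera, shot = shot, row = g$row, col = g$col,
          u = uv[, 1], v = uv[, 2])
      }
    }
    list(corners = do.call(rbind, rows), truth = truth)
  })
}

#' Write a complete simulated session to disk
#'
#' Produces an on-disk capture bundle reproducing the acquisition layout:
#' depth frames (`captures/NNN_depth.npy`), per-frame pose and oracle-ROI
#' JSON (`captures/NNN_poses.json`), the MR surface (`mr/head_surface.ply`),
#' and `ground_truth.json` (head pose, calibration `M`, per-frame true `C`,
#' landmarks) for closed-loop evaluation.
#'
#' @param scene a [simScene()].
#' @param dir output directory (created).
#' @param nFrames number of registration frames.
#' @param offsets optional list of per-frame camera offsets (world mm).
#' @param seed RNG seed.
#' @param noiseless render without noise.
#' @return `dir`, invisibly.
#' @export
simulateSession <- function(scene, dir, nFrames = 5L, offsets = NULL, seed = 1L,
                            noiseless = FALSE) {
  dir.create(file.path(dir, "captures"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "mr"), recursive = TRUE, showWarnings = FALSE)
  if (is.null(offsets)) offsets <- rep(list(c(0, 0, 0)), nFrames)
  writePly(scene$surface, file.path(dir, "mr", "head_surface.ply"))
  Ctrue <- vector("list", length(offsets))
  for (i in seq_along(offsets)) {
    cap <- renderDepth(scene, cameraOffset = offsets[[i]], seed = childSeed(seed, i),
                       noiseless = noiseless)
    writeNpy(cap$frame@depth, file.path(dir, "captures", sprintf("%03d_depth.npy", i)))
    jsonlite::write_json(list(C = as.numeric(t(transformMatrix(cap$C))),
                              roi = cap$roi@bbox,
                              timestamp = cap$frame@timestamp),
                         file.path(dir, "captures", sprintf("%03d_poses.json", i)),
                         auto_unbox = TRUE, digits = NA)
    Ctrue[[i]] <- as.numeric(t(transformMatrix(cap$Ctrue)))
  }
  jsonlite::write_json(list(
    headPose = as.numeric(t(transformMatrix(scene$headPose))),
    M = as.numeric(t(transformMatrix(scene$M))),
    Ctrue = Ctrue,
    landmarks = unname(apply(scene$landmarks, 1, as.numeric, simplify = FALSE)),
    seed = scene$seed),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
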