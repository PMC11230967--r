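test_that("detectMarkers finds saturated blobs with sub-pixel centroids", {
  expect_equal(nrow(detectMarkers(matrix(0, 50, 50))@centroids), 0L)
  img <- matrix(0, 50, 50)
  img[21, 11] <- 1  # row 20, col 10 (0-based)
  obs <- detectMarkers(img, minArea = 1L, refineMargin = 0L)
  expect_equal(as.numeric(obs@centroids[1, ]), c(10, 20))
  # rendered blobs at known sub-pixel centres on the IR-sized sensor
  set.seed(21)
  centres <- cbind(runif(4, 100, 540), runif(4, 100, 476))
  img <- matrix(0, 576, 640)
  for (i in 1:4) img <- SurfNav:::stampMarker(img, centres[i, 1], centres[i, 2], 3)
  obs <- detectMarkers(img)
  expect_equal(nrow(obs@centroids), 4L)
  ord <- order(obs@centroids[, 1]); ordTrue <- order(centres[, 1])
  expect_lt(max(abs(obs@centroids[ord, ] - centres[ordTrue, ])), 0.3)
})

test_that("correspondences follow the descending-x / ascending-u rule", {
  X <- cbind(c(120, 80, 40), 0, 0)
  obs <- new("MarkerObservation", centroids = cbind(c(310, 590, 50), c(0, 0, 0)),
             pixelCounts = rep(5L, 3), mergedSuspect = rep(FALSE, 3))
  corr <- orderCorrespondences(obs, X)
  expect_equal(corr$X[, 1], c(120, 80, 40))
  expect_equal(corr$pixels[, 1], c(50, 310, 590))
  # single marker
  obs1 <- new("MarkerObservation", centroids = cbind(10, 20),
              pixelCounts = 4L, mergedSuspect = FALSE)
  corr1 <- orderCorrespondences(obs1, cbind(5, 1, 2))
  expect_equal(nrow(corr1$X), 1L)
  # pairing is invariant to a seeded permutation of the input order
  set.seed(22)
  pX <- sample(3); pU <- sample(3)
  obsP <- new("MarkerObservation", centroids = obs@centroids[pU, ],
              pixelCounts = rep(5L, 3), mergedSuspect = rep(FALSE, 3))
  corrP <- orderCorrespondences(obsP, X[pX, ])
  expect_equal(corrP, corr)
  # count mismatch and ties
  expect_error(orderCorrespondences(obs1, X), "correspondence error")
  Xtie <- cbind(c(50, 50, 40), c(0, 10, 20), 0)
  expect_error(orderCorrespondences(obs, Xtie), "ambiguous")
  expect_error(orderCorrespondences(obs, cbind(c(120, 80, 40), c(0, 30, 0), 0)),
               "collinear")
})

test_that("solvePnp recovers an exact pose and flags degeneracy", {
  cam <- irCameraDefault()
  set.seed(23)
  X <- matrix(rnorm(18, 0, 80), ncol = 3)  # 6 non-coplanar points
  V <- rigidTransform(rotationVectorToMatrix(c(0.12, -0.1, 0.08)), c(30, -20, -500),
                      frameFrom = "optical", frameTo = "tracker")
  Xopt <- transformPoints(invert(V), X)
  stopifnot(all(Xopt[, 3] > 0))
  uv <- projectPoints(cam, Xopt)
  Vhat <- solvePnp(X, uv, cam)
  expect_transform_equal(Vhat, V, 1e-6, 1e-8)
  # points expressed in the optical frame, identity pose
  Xo <- cbind(matrix(rnorm(12, 0, 60), ncol = 2), runif(6, 400, 700))
  Vi <- solvePnp(Xo, projectPoints(cam, Xo), cam,
                 worldFrame = "optical", opticalFrame = "optical")
  expect_transform_equal(Vi, identityTransform("optical"), 1e-6, 1e-8)
  expect_error(solvePnp(X[1:3, ], uv[1:3, ], cam), "at least 4")
  Xcol <- cbind(seq(0, 120, length.out = 5), 0, 0)
  Vc <- rigidTransform(diag(3), c(0, 0, -500), frameFrom = "optical", frameTo = "t")
  uvc <- projectPoints(cam, transformPoints(invert(Vc), Xcol))
  expect_error(solvePnp(Xcol, uvc, cam), "collinear")
})

test_that("the calibration identity M = C^-1 V holds in closed form", {
  expect_transform_equal(calibrationFromPoses(identityTransform("body", "tracker"),
                                              identityTransform("optical", "tracker")),
                         identityTransform("optical", "body"), 1e-15, 1e-12)
  C <- rigidTransform(diag(3), c(0, 0, 100), "body", "tracker")
  V <- identityTransform("optical", "tracker")
  M <- calibrationFromPoses(C, V)
  expect_equal(transformMatrix(M)[1:3, 4], c(0, 0, -100))
})

test_that("noiseless simulated captures recover the true M to numerical precision", {
  sc <- noiselessScene()
  caps <- simulateTrackingCaptures(sc, n = 20L, seed = 1L, noiseless = TRUE)
  cal <- calibrateTracking(caps, sc$camera)
  expect_lt(translationDistance(trackingMatrix(cal), sc$M), 1e-6)
  expect_lt(rotationAngleBetween(trackingMatrix(cal), sc$M), 1e-6)
  expect_lt(mean(cal@rmsePerCapture), 1e-6)
  assign("noiselessCaps", caps, envir = .fixtures)
  assign("noiselessCal", cal, envir = .fixtures)
})

test_that("reprojection RMSE equals a closed form under an injected pixel offset", {
  sc <- noiselessScene()
  caps <- get("noiselessCaps", envir = .fixtures)
  cal <- get("noiselessCal", envir = .fixtures)
  # +1 px horizontal offset on every centroid is +1 px RMSE
  capOff <- caps[[1]]
  corr <- SurfNav:::captureCorrespondences(capOff)
  CM <- transformMatrix(capOff@cameraBodyPose) %*% transformMatrix(trackingMatrix(cal))
  W <- solve(CM)
  Xopt <- sweep(corr$X %*% t(W[1:3, 1:3]), 2, -W[1:3, 4], "-")
  uv <- projectPoints(sc$camera, Xopt)
  rmseDirect <- sqrt(mean(rowSums((uv - corr$pixels)^2)))
  expect_equal(reprojectionRmse(cal, caps[1], sc$camera), rmseDirect, tolerance = 1e-9)
  uvOff <- uv; uvOff[, 1] <- uvOff[, 1] + 1
  expect_equal(sqrt(mean(rowSums((uvOff - corr$pixels)^2))),
               sqrt(rmseDirect^2 + 1), tolerance = 1e-6)
})

test_that("calibration is invariant to a rigid re-labelling of the tracker world", {
  sc <- noiselessScene()
  caps <- get("noiselessCaps", envir = .fixtures)[1:8]
  cal <- calibrateTracking(caps, sc$camera)
  set.seed(24)
  W <- randomTransform(frameFrom = "tracker", frameTo = "tracker")
  capsW <- lapply(caps, function(cap) {
    new("CalibrationCapture", irImage = cap@irImage,
        cameraBodyPose = compose(W, cap@cameraBodyPose),
        toolMarkerPositions = transformPoints(W, cap@toolMarkerPositions))
  })
  calW <- calibrateTracking(capsW, sc$camera)
  expect_transform_equal(trackingMatrix(calW), trackingMatrix(cal), 1e-6, 1e-8)
})

test_that("more noiseless captures never worsen the recovered M", {
  sc <- noiselessScene()
  caps <- get("noiselessCaps", envir = .fixtures)
  err <- function(cal) translationDistance(trackingMatrix(cal), sc$M)
  e5 <- err(calibrateTracking(caps[1:5], sc$camera))
  e20 <- err(calibrateTracking(caps, sc$camera))
  expect_lte(e20, e5 + 1e-7)
})
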