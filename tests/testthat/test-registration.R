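test_that("RANSAC initialisation aligns a cloud to itself and to a moved copy", {
  face <- noiselessMrFace()
  cloud <- face$cloud
  idT <- ransacInitialTransform(cloud, cloud, seed = 71)
  expect_lt(translationDistance(idT, identityTransform("virtual")), 1)
  expect_lt(rotationAngleBetween(idT, identityTransform("virtual")) * 180 / pi, 1)
  # a 30 degree / 200 mm displacement is recovered well inside the ICP basin
  set.seed(71)
  ax <- c(0.2, 0.93, 0.3); ax <- ax / sqrt(sum(ax^2))
  Tt <- rigidTransform(rotationVectorToMatrix(ax * 30 * pi / 180),
                       c(120, -90, 120), frameFrom = "virtual", frameTo = "moved")
  moved <- transformPoints(Tt, cloud)
  got <- ransacInitialTransform(cloud, moved, seed = 72)
  expect_lt(translationDistance(got, Tt), 5)
  expect_lt(rotationAngleBetween(got, Tt) * 180 / pi, 5)
  expect_error(ransacInitialTransform(pointCloud(matrix(rnorm(6), 2, 3)), cloud),
               "at least 3")
})

test_that("ICP is exact on identical clouds and recovers seeded transforms", {
  face <- noiselessMrFace()
  cloud <- face$cloud
  res0 <- icpRefine(cloud, cloud, identityTransform("virtual"))
  expect_lt(translationDistance(res0@T, identityTransform("virtual")), 1e-9)
  expect_lt(res0@icpRmse, 1e-9)
  expect_true(res0@converged)
  set.seed(73)
  Tt <- rigidTransform(rotationVectorToMatrix(rnorm(3, 0, 0.05)), rnorm(3, 0, 5),
                       frameFrom = "virtual", frameTo = "moved")
  moved <- pointCloud(transformPoints(Tt, cloudPoints(cloud)), "moved")
  init <- rigidTransform(rotationVectorToMatrix(rnorm(3, 0, 0.003)) %*%
                           transformMatrix(Tt)[1:3, 1:3],
                         transformMatrix(Tt)[1:3, 4] + rnorm(3, 0, 1),
                         frameFrom = "virtual", frameTo = "moved")
  res <- icpRefine(cloud, moved, init, tol = 1e-12)
  expect_lt(translationDistance(res@T, Tt), 1e-6)
  expect_lt(rotationAngleBetween(res@T, Tt), 1e-6)
})

test_that("ICP inlier RMSE never increases across iterations", {
  face <- noiselessMrFace()
  cloud <- face$cloud
  set.seed(74)
  pts <- cloudPoints(cloud) + matrix(rnorm(length(cloudPoints(cloud)), 0, 1), ncol = 3)
  src <- pointCloud(pts, "virtual")
  rmses <- c()
  Tm <- identityTransform("virtual")
  for (it in 1:12) {
    r <- icpRefine(src, cloud, Tm, maxIterations = 1L, tol = 0)
    rmses <- c(rmses, r@icpRmse)
    Tm <- r@T
  }
  expect_true(all(diff(rmses) <= 1e-9))
})

test_that("noisy-cloud ICP averages to sub-half-millimetre translation error", {
  face <- noiselessMrFace()
  target <- face$cloud
  base <- cloudPoints(target)
  set.seed(75)
  errs <- vapply(1:25, function(k) {
    idx <- sample(nrow(base), 2000, replace = TRUE)
    noisy <- base[idx, ] + matrix(rnorm(6000, 0, 1), ncol = 3)
    res <- icpRefine(pointCloud(noisy, "virtual"), target,
                     identityTransform("virtual"), tol = 1e-8)
    translationDistance(res@T, identityTransform("virtual"))
  }, numeric(1))
  expect_lt(mean(errs), 0.5)
})

test_that("chainWorldPose composes G = C M T^-1 with frame checking", {
  I <- identityTransform
  expect_transform_equal(chainWorldPose(I("optical", "MR"), I("body", "tracker"),
                                        I("optical", "body")),
                         I("MR", "tracker"), 1e-15, 1e-12)
  set.seed(76)
  C <- randomTransform(frameFrom = "body", frameTo = "tracker")
  M <- randomTransform(frameFrom = "optical", frameTo = "body")
  G <- chainWorldPose(I("optical", "MR"), C, M)
  expect_lt(max(abs(transformMatrix(G) -
                      transformMatrix(C) %*% transformMatrix(M))), 1e-9)
  expect_error(chainWorldPose(I("optical", "MR"), C,
                              randomTransform(frameFrom = "x", frameTo = "y")),
               "frame mismatch")
})

test_that("the pose filter initialises, contracts, and beats raw noise", {
  f <- poseFilter()
  set.seed(77)
  G0 <- randomTransform(frameFrom = "MR", frameTo = "tracker")
  f <- kalmanUpdate(f, G0)
  expect_transform_equal(filteredPose(f), G0, 1e-12, 1e-12)
  # repeated constant measurement: mean converges, covariance contracts
  trP <- sum(diag(f@Pt))
  for (k in 1:30) {
    f <- kalmanUpdate(f, G0)
    expect_lte(sum(diag(f@Pt)), trP + 1e-9)
    trP <- sum(diag(f@Pt))
  }
  expect_transform_equal(filteredPose(f), G0, 1e-9, 1e-9)
  # noisy measurements of a fixed pose: steady state below sigma/3, and the
  # translation tracks an independent covariance-weighted running average
  sigmaT <- 5; sigmaR <- 1 * pi / 180
  f <- poseFilter(processNoise = c(0, 0),
                  measurementNoise = c(sigmaT^2, sigmaR^2))
  zs <- list()
  for (k in 1:100) {
    Rz <- rotationVectorToMatrix(rnorm(3, 0, sigmaR / sqrt(3))) %*%
      transformMatrix(G0)[1:3, 1:3]
    tz <- transformMatrix(G0)[1:3, 4] + rnorm(3, 0, sigmaT / sqrt(3))
    zs[[k]] <- rigidTransform(Rz, tz, "MR", "tracker")
    f <- kalmanUpdate(f, zs[[k]])
  }
  est <- filteredPose(f)
  expect_lt(translationDistance(est, G0), sigmaT / 3)
  runningMean <- Reduce(`+`, lapply(zs, function(z) transformMatrix(z)[1:3, 4])) / 100
  expect_lt(max(abs(transformMatrix(est)[1:3, 4] - runningMean)), 0.15)
})

test_that("a static noiseless stream yields identical per-frame transforms", {
  sc <- noiselessScene()
  mrFace <- noiselessMrFace()
  frames <- lapply(1:4, function(i) {
    cap <- renderDepth(sc, seed = i, noiseless = TRUE)
    list(cloud = extractFaceCloud(cap$frame, cap$roi), C = cap$C)
  })
  st <- registerStream(frames, mrFace, sc$M, targetMesh = sc$surface,
                       variant = "point-to-plane", downsample = "sample")
  expect_length(st$failed, 0L)
  for (i in 2:4)
    expect_transform_equal(st$results[[i]]@T, st$results[[1]]@T, 1e-6, 1e-8)
  for (i in 1:4)
    expect_transform_equal(st$G[[i]], sc$headPose, 1e-6, 1e-8)
})

test_that("stream registration is deterministic given seeds", {
  sc <- noisyScene()
  mrFace <- extractMrFace(sc$surface)
  frames <- lapply(1:2, function(i) {
    cap <- renderDepth(sc, seed = i)
    list(cloud = extractFaceCloud(cap$frame, cap$roi, sc$correction), C = cap$C)
  })
  st1 <- registerStream(frames, mrFace, sc$M, ransacSeed = 5L)
  st2 <- registerStream(frames, mrFace, sc$M, ransacSeed = 5L)
  expect_equal(transformMatrix(st1$G[[2]]), transformMatrix(st2$G[[2]]))
})
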