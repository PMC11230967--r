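test_that("the parametric head has head-like principal structure and is deterministic", {
  h1 <- generateHead(7)
  ev <- eigen(cov(vertices(h1$surface)), symmetric = TRUE, only.values = TRUE)$values
  expect_gt(ev[1] / ev[2], 1.1)
  expect_gt(ev[2] / ev[3], 1.05)
  h2 <- generateHead(7)
  expect_identical(vertices(h1$surface), vertices(h2$surface))
  expect_identical(triangles(h1$surface), triangles(h2$surface))
  expect_false(identical(vertices(generateHead(8)$surface), vertices(h1$surface)))
  expect_warning(generateHead(7, semiAxes = c(80, 80, 80), noseAmplitude = 0),
                 "isotropic")
  # nose tip lies on the +z face side
  expect_gt(h1$landmarks["noseTip", 3], 80)
})

test_that("the head mesh is watertight (every edge shared by exactly two triangles)", {
  h <- generateHead(1)
  F <- triangles(h$surface)
  edges <- rbind(F[, 1:2], F[, 2:3], F[, c(3, 1)])
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  expect_true(all(table(key) == 2L))
})

test_that("noiseless depth rendering of a plane is exact and noisy moments are correct", {
  sc <- noiselessScene()
  # fronto-parallel plane 500 mm in front of the camera, as an MR-frame mesh
  Rw <- transformMatrix(sc$baseOptical)
  cornersOpt <- rbind(c(-400, -400, 500), c(400, -400, 500),
                      c(400, 400, 500), c(-400, 400, 500))
  cornersW <- transformPoints(rigidTransform(Rw, frameFrom = "optical",
                                             frameTo = "tracker"), cornersOpt)
  cornersMr <- transformPoints(invert(sc$headPose), cornersW)
  plane <- mrSurface(cornersMr, rbind(c(1L, 2L, 3L), c(1L, 3L, 4L)))
  cap <- renderDepth(sc, seed = 1, noiseless = TRUE, mesh = plane)
  d <- depthValues(cap$frame)
  expect_gt(sum(d > 0), 1e5)
  expect_lt(max(abs(d[d > 0] - 500)), 1e-9)
  # with noise on: mean = 500 + systematic bias, sd within 5%
  scN <- noisyScene()
  capN <- renderDepth(scN, seed = 2, mesh = plane)
  dN <- depthValues(capN$frame)
  v <- dN[dN > 0]
  bias <- 5 + 0.01 * 500
  n <- length(v)
  expect_lt(abs(mean(v) - (500 + bias)), 3 * scN$noise$depthRandomSd / sqrt(n))
  expect_lt(abs(sd(v) - scN$noise$depthRandomSd) / scN$noise$depthRandomSd, 0.05)
})

test_that("a plane-sweep fit removes the injected systematic bias", {
  scN <- noisyScene()
  sweepData <- simulatePlaneSweep(scN, reps = 25, seed = 4)
  corr <- fitDepthCorrection(sweepData)
  stations <- seq(250, 1050, by = 50)
  raw <- stations + 5 + 0.01 * stations
  corrected <- SurfNav:::polyEval(corr@coefficients, raw)
  expect_lt(max(abs(corrected - stations)), 1)   # residual systematic bias < 1 mm
})

test_that("calibration captures are deterministic and record ground truth", {
  sc <- noiselessScene()
  caps1 <- simulateTrackingCaptures(sc, n = 3, seed = 9, noiseless = TRUE)
  caps2 <- simulateTrackingCaptures(sc, n = 3, seed = 9, noiseless = TRUE)
  expect_identical(caps1[[2]]@irImage, caps2[[2]]@irImage)
  expect_s4_class(attr(caps1[[1]], "Vtrue"), "RigidTransform")
  # merged-blob flag: stamp two markers within a pixel of each other
  img <- matrix(0, 576, 640)
  img <- SurfNav:::stampMarker(img, 300, 300, 3)
  img <- SurfNav:::stampMarker(img, 300.8, 300.4, 3)
  for (u in c(100, 250, 480)) img <- SurfNav:::stampMarker(img, u, 150.3, 3)
  obs <- detectMarkers(img)
  expect_equal(nrow(obs@centroids), 4L)
  expect_true(any(obs@mergedSuspect))
})

test_that("depth noise injection is seed-deterministic", {
  sc <- noisyScene()
  a <- renderDepth(sc, seed = 11)
  b <- renderDepth(sc, seed = 11)
  expect_identical(depthValues(a$frame), depthValues(b$frame))
  c2 <- renderDepth(sc, seed = 12)
  expect_false(identical(depthValues(a$frame), depthValues(c2$frame)))
})

test_that("a session bundle replays through the pipeline to the true pose", {
  sc <- noiselessScene()
  dir <- file.path(tempdir(), "bundle-test")
  unlink(dir, recursive = TRUE)
  simulateSession(sc, dir, nFrames = 2, seed = 1, noiseless = TRUE)
  expect_equal(length(list.files(file.path(dir, "captures"), "_depth")), 2L)
  bundle <- readCaptureBundle(dir)
  expect_s4_class(bundle$surface, "MRSurface")
  gt <- bundle$groundTruth
  headPose <- rigidTransform(matrix(gt$headPose, 4, 4, byrow = TRUE),
                             frameFrom = "MR", frameTo = "tracker")
  M <- rigidTransform(matrix(gt$M, 4, 4, byrow = TRUE),
                      frameFrom = "optical", frameTo = "body")
  frames <- lapply(bundle$frames, function(fr)
    list(cloud = extractFaceCloud(fr$frame, fr$roi), C = fr$C))
  mrFace <- extractMrFace(bundle$surface)
  st <- registerStream(frames, mrFace, M, targetMesh = bundle$surface,
                       variant = "point-to-plane", downsample = "sample")
  expect_transform_equal(st$G[[1]], headPose, 1e-6, 1e-8)
  unlink(dir, recursive = TRUE)
})

test_that("the 5x5 protocol emits 25 registration positions", {
  sc <- noiselessScene()
  offsets <- expand.grid(dx = (-2:2) * 100, dy = (-2:2) * 100)
  expect_equal(nrow(offsets), 25L)
  # bookkeeping only: the full experiment is exercised at smaller scale elsewhere
  dir <- file.path(tempdir(), "bundle-grid")
  unlink(dir, recursive = TRUE)
  simulateSession(sc, dir, offsets = lapply(1:3, function(i) c(i * 50, 0, 0)),
                  seed = 2, noiseless = TRUE)
  expect_equal(length(list.files(file.path(dir, "captures"), "_depth")), 3L)
  unlink(dir, recursive = TRUE)
})
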