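test_that("depth-correction fitting recovers exact and noisy generating curves", {
  stations <- seq(250, 1050, by = 50)  # 17 stations over the 80 cm protocol range
  # unbiased data: coefficients are the identity
  m0 <- cbind(stations, stations)
  c0 <- fitDepthCorrection(m0)
  expect_equal(c0@coefficients, c(0, 1, 0), tolerance = 1e-9)
  expect_lt(c0@residualRmse, 1e-9)
  # known linear bias: true = raw - (5 + 0.01 raw), one rep, noiseless
  raw <- (stations + 5) / 0.99
  m1 <- cbind(stations, raw)
  c1 <- fitDepthCorrection(m1)
  expect_equal(c1@coefficients, c(-5, 0.99, 0), tolerance = 1e-9)
  # Gaussian noise, 25 reps: recovery within 3 standard errors
  set.seed(51)
  trueRep <- rep(stations, each = 25)
  rawRep <- (trueRep + 5) / 0.99 + rnorm(length(trueRep), 0, 1)
  cn <- fitDepthCorrection(cbind(trueRep, rawRep))
  expect_lt(abs(cn@coefficients[1] - (-5)) / cn@stdErrors[1], 3)
  expect_lt(abs(cn@coefficients[2] - 0.99) / cn@stdErrors[2], 3)
  expect_error(fitDepthCorrection(cbind(c(1, 2), c(1, 2))), "distinct")
})

test_that("a non-monotone fit is refused with a downgrade suggestion", {
  x <- c(100, 200, 300, 400, 500)
  y <- c(100, 260, 300, 260, 100)   # forces a downward parabola
  expect_error(fitDepthCorrection(cbind(y, x)), "monotone")
})

test_that("unbiased-data coefficient intervals cover the identity", {
  set.seed(52)
  stations <- seq(250, 1050, by = 50)
  trueRep <- rep(stations, each = 25)
  rawRep <- trueRep + rnorm(length(trueRep), 0, 1)
  fit <- fitDepthCorrection(cbind(trueRep, rawRep))
  ci <- cbind(fit@coefficients - 3 * fit@stdErrors, fit@coefficients + 3 * fit@stdErrors)
  expect_true(ci[1, 1] <= 0 && 0 <= ci[1, 2])
  expect_true(ci[2, 1] <= 1 && 1 <= ci[2, 2])
  expect_true(ci[3, 1] <= 0 && 0 <= ci[3, 2])
})

test_that("applying a correction preserves invalid pixels and matches a scalar oracle", {
  cam <- cameraModel(50, 50, 20, 15, 40, 30)
  set.seed(53)
  d <- matrix(runif(1200, 300, 900), 30, 40)
  d[sample(1200, 100)] <- 0
  fr <- depthFrame(d, cam)
  idc <- identityDepthCorrection(c(100, 1000))
  expect_equal(depthValues(applyDepthCorrection(fr, idc)), d)
  plus5 <- new("DepthCorrection", coefficients = c(5, 1), fitRange = c(100, 1000),
               residualRmse = 0, stdErrors = c(0, 0))
  out5 <- applyDepthCorrection(fr, plus5)
  expect_equal(depthValues(out5)[d > 0], d[d > 0] + 5)
  expect_equal(depthValues(out5)[d == 0], d[d == 0])
  quad <- new("DepthCorrection", coefficients = c(2, 0.98, 1e-5),
              fitRange = c(100, 1000), residualRmse = 0, stdErrors = rep(0, 3))
  out <- depthValues(applyDepthCorrection(fr, quad))
  for (i in sample(which(d > 0), 25)) {
    x <- d[i]
    expect_equal(out[i], 2 + 0.98 * x + 1e-5 * x^2, tolerance = 1e-12)
  }
  # out-of-range pixels are corrected but counted
  dd <- d; dd[dd > 0] <- 2000
  expect_equal(attr(applyDepthCorrection(depthFrame(dd, cam), quad), "nOutOfRange"),
               sum(dd > 0))
})

test_that("ROI projection through a homography matches the corner-mapping oracle", {
  cam <- irCameraDefault()
  roi <- faceROI(c(100, 80, 300, 260))
  idH <- homography(diag(3), "RGB", "IR")
  expect_equal(projectRoiToDepth(roi, idH, cam)@bbox, roi@bbox)
  Hs <- homography(diag(c(0.5, 0.5, 1)), "RGB", "IR")
  expect_equal(projectRoiToDepth(roi, Hs, cam)@bbox, roi@bbox / 2)
  set.seed(54)
  H <- diag(3)
  H[1:2, 1:3] <- H[1:2, 1:3] + matrix(rnorm(6, 0, 0.02), 2, 3)
  H[3, 1:2] <- rnorm(2, 0, 2e-5)
  h <- homography(H, "RGB", "IR")
  got <- projectRoiToDepth(roi, h, cam)@bbox
  b <- roi@bbox
  corners <- applyHomography(h, rbind(c(b[1], b[2]), c(b[3], b[2]),
                                      c(b[3], b[4]), c(b[1], b[4])))
  want <- c(max(min(corners[, 1]), 0), max(min(corners[, 2]), 0),
            min(max(corners[, 1]), cam@width - 1), min(max(corners[, 2]), cam@height - 1))
  expect_equal(got, want, tolerance = 1e-12)
  Hfar <- diag(3); Hfar[1, 3] <- 5000
  expect_error(projectRoiToDepth(roi, homography(Hfar, "RGB", "IR"), cam), "empty ROI")
})

test_that("face extraction unprojects exactly the valid in-ROI pixels", {
  cam <- irCameraDefault()
  d <- matrix(0, cam@height, cam@width)
  d[200:299, 250:349] <- 500   # fronto-parallel plane at 500 mm
  fr <- depthFrame(d, cam)
  roi <- faceROI(c(249, 199, 348, 298))  # 0-based bounds of the block
  cloud <- extractFaceCloud(fr, roi)
  expect_equal(nrow(cloudPoints(cloud)), 100L * 100L)
  expect_true(all(abs(cloudPoints(cloud)[, 3] - 500) < 1e-9))
  expect_identical(cloudFrame(cloud), "optical")
  expect_error(extractFaceCloud(fr, faceROI(c(0, 0, 50, 50))), "insufficient surface")
  # full-image ROI is a superset of any sub-ROI
  full <- extractFaceCloud(fr, faceROI(c(0, 0, cam@width - 1, cam@height - 1)))
  sub <- extractFaceCloud(fr, faceROI(c(260, 210, 320, 270)))
  keyF <- apply(round(cloudPoints(full), 9), 1, paste, collapse = ",")
  keyS <- apply(round(cloudPoints(sub), 9), 1, paste, collapse = ",")
  expect_true(all(keyS %in% keyF))
})

test_that("voxel downsampling is order-independent and surface-preserving in sample mode", {
  set.seed(55)
  pts <- matrix(rnorm(900, 0, 40), ncol = 3)
  a <- voxelDownsample(pts, 10)
  b <- voxelDownsample(pts[sample(nrow(pts)), ], 10)
  keyA <- apply(round(a, 9), 1, paste, collapse = ",")
  keyB <- apply(round(b, 9), 1, paste, collapse = ",")
  expect_setequal(keyA, keyB)
  s <- voxelDownsample(pts, 10, method = "sample")
  keyP <- apply(round(pts, 9), 1, paste, collapse = ",")
  expect_true(all(apply(round(s, 9), 1, paste, collapse = ",") %in% keyP))
})
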