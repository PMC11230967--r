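test_that("compose matches an element-wise matrix-product oracle and chains frames", {
  expect_transform_equal(compose(identityTransform("a", "b"), identityTransform("a")),
                         identityTransform("a", "b"), 1e-15, 1e-12)
  Tz <- rigidTransform(diag(3), c(0, 0, 100), "a", "b")
  expect_transform_equal(compose(invert(Tz), Tz), identityTransform("a"), 1e-12, 1e-12)
  set.seed(11)
  for (k in 1:10) {
    A <- randomTransform(frameFrom = "x", frameTo = "y")
    B <- randomTransform(frameFrom = "w", frameTo = "x")
    C <- compose(A, B)
    expect_lt(max(abs(transformMatrix(C) -
                        naiveMatmul(transformMatrix(A), transformMatrix(B)))), 1e-12)
    expect_identical(frameFrom(C), "w")
    expect_identical(frameTo(C), "y")
  }
  expect_error(compose(randomTransform(frameFrom = "p", frameTo = "q"),
                       randomTransform(frameFrom = "r", frameTo = "s")),
               "frame mismatch")
})

test_that("invert is the closed-form SE(3) inverse", {
  Tz <- rigidTransform(diag(3), c(0, 0, 100), "a", "b")
  expect_equal(transformMatrix(invert(Tz))[1:3, 4], c(0, 0, -100))
  expect_identical(frameFrom(invert(Tz)), "b")
  set.seed(12)
  for (k in 1:10) {
    A <- randomTransform()
    expect_lt(max(abs(transformMatrix(compose(A, invert(A))) - diag(4))), 1e-9)
  }
})

test_that("SE(3) composition is associative on seeded random triples", {
  set.seed(13)
  for (k in 1:10) {
    A <- randomTransform(frameFrom = "c", frameTo = "d")
    B <- randomTransform(frameFrom = "b", frameTo = "c")
    C <- randomTransform(frameFrom = "a", frameTo = "b")
    lhs <- compose(compose(A, B), C)
    rhs <- compose(A, compose(B, C))
    expect_lt(max(abs(transformMatrix(lhs) - transformMatrix(rhs))), 1e-9)
  }
})

test_that("RigidTransform validity rejects malformed inputs", {
  expect_error(rigidTransform(matrix(2 * diag(3), 3, 3), c(0, 0, 0)), "orthonormal")
  bad <- diag(4); bad[4, 1] <- 1
  expect_error(new("RigidTransform", matrix = bad, frameFrom = "a", frameTo = "b"),
               "last row")
})

test_that("projection hits the principal point on axis and the pinhole closed form", {
  cam <- cameraModel(600, 600, 320, 288, 640, 576)
  expect_equal(as.numeric(projectPoints(cam, c(0, 0, 500))), c(320, 288))
  expect_equal(projectPoints(cam, c(500, 0, 500))[1, 1], 320 + 600)
  expect_error(projectPoints(cam, c(0, 0, -5)), "behind")
})

test_that("rational distortion follows the scalar formula and is identity at zero", {
  d <- c(k1 = -0.1, k2 = 0.02, k3 = -0.002, k4 = 0.05, k5 = -0.01, k6 = 0.001,
         p1 = 1e-4, p2 = -2e-4)
  cam <- cameraModel(600, 600, 320, 288, 640, 576, distortion = d)
  x <- 0.1; y <- 0
  r2 <- x^2 + y^2
  radial <- (1 + d[1] * r2 + d[2] * r2^2 + d[3] * r2^3) /
            (1 + d[4] * r2 + d[5] * r2^2 + d[6] * r2^3)
  xd <- x * radial + 2 * d[7] * x * y + d[8] * (r2 + 2 * x^2)
  uv <- projectPoints(cam, c(x * 500, y * 500, 500))
  expect_equal(uv[1, 1], unname(600 * xd + 320), tolerance = 1e-12)
  cam0 <- cameraModel(600, 600, 320, 288, 640, 576)
  xy <- matrix(runif(20, -0.3, 0.3), ncol = 2)
  expect_equal(SurfNav:::distortNormalized(cam0, xy), xy, tolerance = 1e-12)
})

test_that("unprojection returns z-depth points and round-trips through projection", {
  cam <- cameraModel(600, 600, 320, 288, 640, 576)
  expect_equal(as.numeric(unprojectPixels(cam, c(320, 288), 500)), c(0, 0, 500))
  expect_error(unprojectPixels(cam, c(320, 288), -1), "depth")
  set.seed(14)
  px <- cbind(runif(1000, 0, 639), runif(1000, 0, 575))
  z <- runif(1000, 200, 1500)
  # zero distortion
  rt <- projectPoints(cam, unprojectPixels(cam, px, z))
  expect_lt(max(abs(rt - px)), 1e-6)
  # all eight coefficients nonzero: fixed-point inversion against the forward model
  camd <- cameraModel(600, 600, 320, 288, 640, 576,
                      distortion = c(-0.05, 0.01, -0.001, 0.02, -0.005, 5e-4, 1e-4, -1e-4))
  pts <- unprojectPixels(camd, px, z)
  expect_equal(pts[, 3], z)
  rtd <- projectPoints(camd, pts)
  expect_lt(max(abs(rtd - px)), 1e-4)
})

test_that("homographies map pixels projectively with degenerate-point detection", {
  px <- cbind(c(0, 100, 50), c(0, -20, 30))
  expect_equal(applyHomography(homography(diag(3)), px), px)
  Ht <- diag(3); Ht[1, 3] <- 10; Ht[2, 3] <- -5
  expect_equal(applyHomography(homography(Ht), px), px + rep(c(10, -5), each = 3))
  set.seed(15)
  H <- diag(3) + matrix(rnorm(9, 0, 0.05), 3, 3)
  h <- homography(H)
  rt <- applyHomography(invertHomography(h), applyHomography(h, px))
  expect_lt(max(abs(rt - px)), 1e-9)
  Hdeg <- rbind(c(1, 0, 0), c(0, 1, 0), c(-1 / 50, 0, 1))  # w = 0 at u = 50
  expect_error(applyHomography(homography(Hdeg), cbind(50, 10)), "infinity")
})

test_that("kabschTransform recovers a known rigid map", {
  set.seed(16)
  X <- matrix(rnorm(60, 0, 50), ncol = 3)
  A <- randomTransform()
  Y <- transformPoints(A, X)
  expect_transform_equal(kabschTransform(X, Y), A, 1e-9, 1e-9)
})

test_that("transformPoints checks the frame label of a PointCloud", {
  A <- randomTransform(frameFrom = "optical", frameTo = "world")
  cl <- pointCloud(matrix(rnorm(30), ncol = 3), frame = "other")
  expect_error(transformPoints(A, cl), "frame mismatch")
})
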