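test_that("estimateHomography recovers identity and known seeded maps", {
  set.seed(31)
  src <- cbind(runif(20, 0, 640), runif(20, 0, 576))
  fitI <- estimateHomography(src, src)
  expect_lt(max(abs(homographyMatrix(fitI@homography) - diag(3))), 1e-9)
  expect_lt(fitI@rmse, 1e-9)
  H <- rbind(c(1.05, 0.02, 12), c(-0.03, 0.97, -8), c(1e-5, -2e-5, 1))
  dst <- applyHomography(homography(H), src)
  fit <- estimateHomography(src, dst)
  expect_lt(max(abs(homographyMatrix(fit@homography) - H / H[3, 3])), 1e-9)
  expect_lt(fit@rmse, 1e-9)
  expect_error(estimateHomography(src[1:3, ], dst[1:3, ]), "at least 4")
  colSrc <- cbind(1:6, 2 * (1:6) + 3)
  expect_error(estimateHomography(colSrc, colSrc + 1), "degenerate|rank")
})

test_that("reported RMSE equals a brute-force residual recomputation", {
  set.seed(32)
  g <- expand.grid(col = 1:32, row = 1:25)  # the 32 x 25 corner grid
  src <- cbind(100 + g$col * 80, 80 + g$row * 70)
  H <- rbind(c(0.98, 0.01, 25), c(0.02, 1.03, -14), c(-1e-5, 2e-5, 1))
  dst <- applyHomography(homography(H), src) + matrix(rnorm(2 * nrow(src), 0, 0.5),
                                                      ncol = 2)
  fit <- estimateHomography(src, dst)
  Hf <- homographyMatrix(fit@homography)
  res2 <- vapply(seq_len(nrow(src)), function(i) {
    p <- Hf %*% c(src[i, ], 1)
    sum((p[1:2] / p[3] - dst[i, ])^2)
  }, numeric(1))
  expect_equal(fit@rmse, sqrt(mean(res2)), tolerance = 1e-12)
  expect_equal(fit@nPoints, 800L)
})

test_that("estimation is equivariant to pre-composed similarities (noiseless)", {
  set.seed(33)
  src <- cbind(runif(30, 0, 600), runif(30, 0, 500))
  H <- rbind(c(1.1, -0.04, 5), c(0.06, 0.93, 11), c(2e-5, -1e-5, 1))
  dst <- applyHomography(homography(H), src)
  ang <- 0.3; s <- 1.4
  S <- rbind(c(s * cos(ang), -s * sin(ang), 20), c(s * sin(ang), s * cos(ang), -30),
             c(0, 0, 1))
  srcS <- applyHomography(homography(S), src)
  fitS <- estimateHomography(srcS, dst)
  expected <- H %*% solve(S)
  expect_lt(max(abs(homographyMatrix(fitS@homography) - expected / expected[3, 3])),
            1e-8)
})

test_that("LM refinement never increases the RMSE", {
  set.seed(34)
  src <- cbind(runif(60, 0, 640), runif(60, 0, 576))
  H <- rbind(c(1.02, 0.05, -10), c(-0.01, 0.99, 6), c(1e-5, 1e-5, 1))
  dst <- applyHomography(homography(H), src) + matrix(rnorm(120, 0, 1), ncol = 2)
  raw <- estimateHomography(src, dst, refine = FALSE)
  ref <- estimateHomography(src, dst, refine = TRUE)
  expect_lte(ref@rmse, raw@rmse + 1e-12)
})

test_that("corners rescale by per-axis ratios and round-trip", {
  g <- cornerGrid(cbind(100, 100), 1, 1, "IR")
  expect_equal(upscaleCorners(g, c(640, 576), c(640, 576))@corners, g@corners)
  up <- upscaleCorners(g, c(640, 576), c(3840, 2160))
  expect_equal(as.numeric(up@corners), c(600, 375))
  down <- upscaleCorners(up, c(3840, 2160), c(640, 576))
  expect_equal(down@corners, g@corners, tolerance = 1e-12)
})

test_that("overlayImage warps by inverse resampling", {
  img <- matrix(runif(40 * 30), 30, 40)
  idFit <- estimateHomography(cbind(c(0, 39, 39, 0), c(0, 0, 29, 29)),
                              cbind(c(0, 39, 39, 0), c(0, 0, 29, 29)))
  out <- overlayImage(img, idFit, c(40, 30))
  expect_equal(out, img, tolerance = 1e-9)
  Ht <- diag(3); Ht[1, 3] <- 5   # shift +5 columns
  outT <- overlayImage(img, homography(Ht), c(40, 30))
  expect_equal(outT[, 6:40], img[, 1:35], tolerance = 1e-9)
  expect_true(all(is.na(outT[, 1:5])))
})

test_that("pooled corner tables give one homography per camera pair", {
  shots <- simulateHomographyShots(seed = 41, nShots = 8, noiseSd = 0)
  for (pair in c("IR:RGB", "IR:HS")) {
    fit <- calibrateHomographyFromCorners(shots$corners, pair)
    Htrue <- shots$truth[[pair]]
    expect_lt(max(abs(homographyMatrix(fit@homography) - Htrue / Htrue[3, 3])), 1e-6)
    expect_lt(fit@rmse, 1e-6)
  }
})
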