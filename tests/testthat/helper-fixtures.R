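# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

noiselessScene <- function()
  fixture("noiselessScene", function() simScene(1L, noise = noiselessConfig()))

noisyScene <- function()
  fixture("noisyScene", function() simScene(1L))

noiselessMrFace <- function()
  fixture("noiselessMrFace", function() extractMrFace(noiselessScene()$surface))

childSeedLocal <- function(seed, k)
  as.integer((as.numeric(seed) * 48271 + as.numeric(k) * 9973) %% 2147483399) + 1L

# A random rigid transform drawn from the current RNG stream.
randomTransform <- function(scale = 100, frameFrom = "a", frameTo = "b") {
  rigidTransform(rotationVectorToMatrix(rnorm(3, 0, 0.8)),
                 rnorm(3, 0, scale), frameFrom, frameTo)
}

# Independent 4x4 matrix product, computed element by element (oracle for
# compose()).
naiveMatmul <- function(A, B) {
  C <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) C[i, j] <- sum(A[i, ] * B[, j])
  C
}

expect_transform_equal <- function(A, B, tolTrans = 1e-9, tolRot = 1e-9) {
  expect_lt(translationDistance(A, B), tolTrans)
  expect_lt(rotationAngleBetween(A, B), tolRot)
}
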