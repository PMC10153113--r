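# Weighted-PCA unwrapping axis, UV grid construction, pullback, padding,
# distortion-corrected averaging.

test_that("weighted PCA picks the axis orthogonal to the weight ring", {
  sph <- icosphere(3)
  w <- exp(-(sph@vertices[, 3] / 0.15)^2)  # band around z = 0
  rot <- optimalRotationPCA(sph, w)
  e3 <- rot$Rprime[, 3]
  ang <- acos(min(1, abs(sum(e3 * c(0, 0, 1)))))
  expect_lt(ang, 5 * pi / 180)
  expect_equal(det(rot$Rprime), 1, tolerance = 1e-9)
  expect_equal(det(rot$rotation), 1, tolerance = 1e-9)

  # uniform weights on a symmetric sphere: degenerate, identity fallback
  u <- optimalRotationPCA(sph, rep(1, nVertices(sph)))
  expect_true(u$degenerate)
  expect_equal(u$rotation, diag(3))
  expect_error(optimalRotationPCA(sph, rep(0, nVertices(sph))), "zero")
})

test_that("UV grid pulls back the unit sphere analytically", {
  sph <- icosphere(4)
  g <- buildUVGrid(sph, N = 64)
  N <- 64; M <- 2 * N + 1
  vang <- seq(0, pi, length.out = N)
  expect_lt(max(abs(g@coords[, 17, 3] - cos(vang))), 1e-3)
  expect_identical(g@coords[, 1, ], g@coords[, M, ])
  expect_lt(abs(sum(g@dA[, -M]) - surfaceArea(sph)) / surfaceArea(sph),
            0.02)
  expect_error(buildUVGrid(sph, N = 4), "at least 8")
  w <- g@weights
  expect_lt(max(abs(apply(w, c(1, 2), sum) - 1)), 1e-6)
  expect_gte(min(w), -1e-8)
})

test_that("scalar pullback respects constants, bands and bump areas", {
  sph <- icosphere(4)
  g <- buildUVGrid(sph, N = 64)
  expect_equal(range(pullbackScalar(g, rep(4, nVertices(sph)))), c(4, 4),
               tolerance = 1e-9)
  img <- pullbackScalar(g, sph@vertices[, 3])
  vang <- seq(0, pi, length.out = 64)
  expect_lt(max(abs(img[, 40] - cos(vang))), 1e-3)

  # indicator of one planted bump: compact blob whose dA-weighted area
  # matches the submesh area
  fx <- paramFixture()$fx
  sp <- directParam()
  gf <- buildUVGrid(sp, target = fx$mesh, N = 128)
  ind <- as.numeric(fx$truth == 1)
  blob <- pullbackScalar(gf, ind) > 0.5
  va <- vertexAreas(fx$mesh)
  a3d <- sum(va[fx$truth == 1])
  aUV <- sum(gf@dA[, -ncol(gf@dA)][blob[, -ncol(blob)]])
  expect_lt(abs(aUV - a3d) / a3d, 0.05)
})

test_that("round trip through the grid reproduces a smooth field", {
  sph <- icosphere(4)
  g <- buildUVGrid(sph, N = 96)
  set.seed(3)
  dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
  f <- sin(2 * sph@vertices %*% dir)
  img <- pullbackScalar(g, as.numeric(f))
  # sample the field independently at the grid's 3D coordinates
  truth <- sin(2 * matrix(g@coords, ncol = 3) %*% dir)
  edgeVar <- 2 * meanEdgeLength(sph)  # Lipschitz bound per edge
  expect_lt(max(abs(img - matrix(truth, 96))), 2 * edgeVar)
})

test_that("spherical padding wraps, and crosses the poles with a half
           period shift", {
  img <- matrix(seq_len(48), 6, 8)
  p <- padSpherical(img, 2)
  expect_identical(dim(p), c(10L, 12L))
  expect_identical(p[3:8, 1:2], img[, 7:8])
  expect_identical(p[3:8, 11:12], img[, 1:2])
  half <- 4
  shifted <- img[, c(5:8, 1:4)]
  expect_identical(p[2, 3:10], shifted[2, ])  # row -1 = row 2 shifted
  expect_identical(p[9, 3:10], shifted[5, ])  # below-south mirror
  cst <- padSpherical(matrix(7, 5, 9), 1)
  expect_true(all(cst == 7))
})

test_that("dA-weighted means correct for unwrapping distortion", {
  img <- matrix(3.5, 8, 8)
  dA <- matrix(runif(64) + 0.5, 8, 8)
  msk <- matrix(rep(c(TRUE, FALSE), 32), 8, 8)
  expect_equal(weightedUVMean(img, dA, msk), 3.5)
  # uniform dA: plain masked mean
  img2 <- matrix(rnorm(64), 8, 8)
  expect_equal(weightedUVMean(img2, matrix(1, 8, 8), msk),
               mean(img2[msk]))
  expect_error(weightedUVMean(img2, matrix(1, 8, 8),
                              matrix(FALSE, 8, 8)), "empty")

  # curvature of a planted bump: UV-weighted mean equals the 3D
  # area-weighted mean over the bump submesh
  fx <- paramFixture()$fx
  sp <- directParam()
  gf <- buildUVGrid(sp, target = fx$mesh, N = 256)
  H <- memo("fixtureH", meanCurvatureSDF(fx$mesh))
  va <- vertexAreas(fx$mesh)
  sel <- fx$truth == 2
  h3d <- sum(H[sel] * va[sel]) / sum(va[sel])
  Himg <- pullbackScalar(gf, H)
  blob <- pullbackScalar(gf, as.numeric(sel)) > 0.5
  hUV <- weightedUVMean(Himg, gf@dA, blob)
  expect_lt(abs(hUV - h3d) / abs(h3d), 0.03)
})

test_that("equiareal relaxation flattens the area histogram of the grid", {
  spC <- distortedParam()$sp
  spE <- relaxedDistorted()
  fx <- distortedParam()$fx
  gC <- buildUVGrid(spC, target = fx$mesh, N = 64)
  gE <- buildUVGrid(spE, target = fx$mesh, N = 64)
  vang <- seq(0, pi, length.out = 64)
  sinv <- pmax(sin(vang), 1e-6)
  covOf <- function(g) {
    x <- sweep(g@dA[2:63, -129], 1, sinv[2:63], `/`)
    sd(x) / mean(x)
  }
  expect_lt(covOf(gE), 0.5 * covOf(gC))
})
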