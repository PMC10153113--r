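# Conformalized mean curvature flow, stopping rule, active-contour step,
# topographic flattening.

test_that("cMCF preserves structure, normalization and fixed shapes", {
  sph <- icosphere(4)
  fl <- runCMCF(sph, flowConfig(dt = 5e-4, maxIterations = 3))
  # the sphere is the flow's fixed shape (after area renormalization)
  for (t in 1:3) {
    V <- fl$snapshots[[as.character(t)]]
    expect_lt(max(abs(sqrt(rowSums(V^2)) - 1)), 1e-3)
  }
  expect_identical(fl$faces, sph@faces)

  # dt = 0 reduces the system to the identity
  fl0 <- runCMCF(sph, flowConfig(dt = 0, maxIterations = 1))
  expect_equal(fl0$snapshots[["1"]], sph@vertices, tolerance = 1e-8)

  # area preserved and centroid recentred every iteration
  fx <- paramFixture()$fx
  flb <- runCMCF(fx$mesh, flowConfig(dt = 5e-4, maxIterations = 10))
  a0 <- surfaceArea(fx$mesh)
  cen0 <- colMeans(fx$mesh@vertices)
  for (t in c(3, 10)) {
    snap <- flowSnapshot(flb, t)
    expect_equal(surfaceArea(snap), a0, tolerance = 1e-6)
    expect_lt(max(abs(colMeans(snap@vertices) - cen0)), 1e-6)
  }
  # mean absolute Gaussian curvature decays over the first iterations
  # (allowing numerical jitter at the flat end of the trace)
  expect_true(all(diff(flb$Kbar[1:10]) <= 1e-4 * flb$Kbar[1]))
})

test_that("freezing the Laplacian reduces conformal distortion", {
  fx <- paramFixture()$fx
  cm <- runCMCF(fx$mesh, flowConfig(dt = 5e-4, maxIterations = 10),
                conformalized = TRUE)
  pl <- runCMCF(fx$mesh, flowConfig(dt = 5e-4, maxIterations = 10),
                conformalized = FALSE)
  qc <- faceDistortion(fx$mesh, flowSnapshot(cm, 10))@globalQ
  qp <- faceDistortion(fx$mesh, flowSnapshot(pl, 10))@globalQ
  expect_lt(qc, qp)
})

test_that("automatic stopping rule follows the elbow of the K trace", {
  Kbar <- cumsum(c(1, -1e-3, -1e-4, -5e-6, -1e-6))
  expect_identical(autoStopIndex(Kbar, deltaThresh = 1e-5, tMin = 1L), 3L)
  expect_identical(autoStopIndex(Kbar, deltaThresh = 1e-5, tMin = 10L), 10L)
  # never triggered: last iteration
  K2 <- cumsum(c(1, rep(-0.5, 6)))
  expect_identical(autoStopIndex(K2, deltaThresh = 1e-5, tMin = 1L), 6L)
  # literal mode triggers only on a positive jump above threshold
  K3 <- cumsum(c(1, -0.1, -0.1, 2e-5, -0.1))
  expect_identical(autoStopIndex(K3, deltaThresh = 1e-5, tMin = 1L,
                                 mode = "literal"), 3L)
})

test_that("active-contour stepping displaces along the applied force", {
  s <- icosphere(3, radius = 10)
  # zero force, tiny stiffness: identity
  out0 <- activeContourStep(s, matrix(0, nVertices(s), 3), dt = 1e-12)
  expect_equal(out0@vertices, s@vertices, tolerance = 1e-8)
  # unit outward normal force grows the radius by ~1 voxel
  nrm <- s@vertices / sqrt(rowSums(s@vertices^2))
  up <- activeContourStep(s, nrm, dt = 1e-9)
  expect_lt(abs(mean(sqrt(rowSums(up@vertices^2))) - 11) / 1, 0.1)
  dn <- activeContourStep(s, -nrm, dt = 1e-9)
  expect_lt(abs(mean(sqrt(rowSums(dn@vertices^2))) - 9) / 1, 0.1)
})

test_that("topographic cMCF flattens while pinning boundary (u,v)", {
  flat <- gridMesh(12L, depth = 5)
  out <- topographicCMCF(flat, iterations = 5, delta = 1e4)
  expect_equal(out@vertices, flat@vertices, tolerance = 1e-6)

  g <- gridMesh(12L, depth = 5)
  gr <- expand.grid(v = 1:12, u = 1:12)
  g@vertices[, 1] <- 5 + 4 * exp(-((gr$v - 6)^2 + (gr$u - 6)^2) / 6)
  res <- topographicCMCF(g, iterations = 50, delta = 5e4)
  dev0 <- max(abs(g@vertices[, 1] - mean(g@vertices[, 1])))
  dev1 <- max(abs(res@vertices[, 1] - mean(res@vertices[, 1])))
  expect_lt(dev1, 0.1 * dev0)
  bnd <- boundaryLoops(g@faces)[[1]]
  expect_lt(max(abs(res@vertices[bnd, 2:3] - g@vertices[bnd, 2:3])), 1e-8)

  # multiple boundary loops rejected
  holed <- submeshByFaces(g, setdiff(seq_len(nFaces(g)), 100:101))$mesh
  expect_error(topographicCMCF(holed, 2, 1e3), "one boundary")
})
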