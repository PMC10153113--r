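# Curvature measures, distortion metrics, mesh comparison, face quality.

test_that("radius ratio has the closed-form values", {
  eq <- SurfaceMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0)),
                    rbind(1:3))
  expect_equal(radiusRatio(eq), 1, tolerance = 1e-12)

  # needle triangles approach zero quality
  needle <- SurfaceMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, 1e-4, 0)),
                        rbind(1:3), dropDegenerate = FALSE)
  expect_lt(radiusRatio(needle), 1e-3)

  # right isoceles: r_in = (a + b - c)/2, r_circ = c/2
  iso <- SurfaceMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), rbind(1:3))
  expect_equal(radiusRatio(iso), 2 * (2 - sqrt(2)) / 2 / (sqrt(2) / 2),
               tolerance = 1e-12)
})

test_that("angle-deficit curvature satisfies Gauss-Bonnet", {
  expect_equal(sum(gaussianCurvature(icosphere(2))), 4 * pi,
               tolerance = 1e-6)
  expect_equal(sum(gaussianCurvature(torusMesh())), 0, tolerance = 1e-6)
  # regular tetrahedron: deficit 2*pi - 3*(pi/3) = pi at every vertex
  tet <- SurfaceMesh(rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1),
                           c(-1, -1, 1)),
                     rbind(c(1, 2, 3), c(1, 4, 2), c(1, 3, 4), c(2, 4, 3)))
  expect_equal(gaussianCurvature(tet), rep(pi, 4), tolerance = 1e-12)
  tri <- SurfaceMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), rbind(1:3))
  expect_error(gaussianCurvature(tri), "closed")
})

test_that("SDF mean curvature recovers 1/R on balls across radii", {
  for (R in c(8, 12, 16, 24)) {
    s <- icosphere(3, radius = R, center = rep(R + 8, 3))
    H <- meanCurvatureSDF(s)
    expect_lt(abs(mean(H) - 1 / R) / (1 / R), 0.15)
  }
  # scaling: double the radius, halve the curvature
  H10 <- mean(meanCurvatureSDF(icosphere(3, 10, rep(18, 3))))
  H20 <- mean(meanCurvatureSDF(icosphere(3, 20, rep(28, 3))))
  expect_lt(abs(H20 - H10 / 2) / (H10 / 2), 0.15)
  # flat slab face: |H| ~ 0 away from edges
  box <- array(FALSE, c(40, 40, 24))
  box[6:35, 6:35, 6:19] <- TRUE
  bm <- suppressMessages(meshFromVolume(BinaryVolume(box),
                                        remeshFraction = 0.5))
  Hb <- meanCurvatureSDF(bm)
  V <- vertices(bm)
  faceCenter <- abs(V[, 1] - 20) < 6 & abs(V[, 2] - 20) < 6 & V[, 3] > 17
  expect_lt(max(abs(Hb[faceCenter])), 0.01)
})

test_that("per-face distortion has exact invariances", {
  m <- icosphere(2, radius = 5)
  idrep <- faceDistortion(m, m)
  expect_equal(range(idrep@Q), c(1, 1), tolerance = 1e-9)
  expect_equal(range(idrep@lambda), c(1, 1), tolerance = 1e-9)
  expect_equal(idrep@globalQ, 1, tolerance = 1e-9)

  sc <- m; sc@vertices <- m@vertices * 2
  screp <- faceDistortion(m, sc)
  expect_equal(range(screp@Q), c(1, 1), tolerance = 1e-9)
  expect_equal(range(screp@lambda), c(1, 1), tolerance = 1e-9)

  # single pair, one axis stretched by 2: sigma = (2, 1)
  tri <- SurfaceMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), rbind(1:3))
  tri2 <- tri; tri2@vertices[, 1] <- tri@vertices[, 1] * 2
  expect_equal(faceDistortion(tri, tri2)@globalQ, 2, tolerance = 1e-9)

  # lambda is reciprocal under swap of the mapping direction
  bump <- directParam()
  fwd <- faceDistortion(bump@reference, bump@sphere)
  bwd <- faceDistortion(bump@sphere, bump@reference)
  expect_equal(mean(fwd@lambda * bwd@lambda), 1, tolerance = 1e-8)

  # collapsed destination triangle flagged, excluded from aggregates
  crush <- m
  crush@vertices[faces(m)[1, ], ] <-
    matrix(rep(crush@vertices[faces(m)[1, 1], ], 3), 3, byrow = TRUE)
  crep <- faceDistortion(m, crush)
  expect_gte(crep@nInfinite, 1L)
  expect_true(is.finite(crep@globalQ))
})

test_that("UV grid distortion matches the analytic equirectangular map", {
  g <- buildUVGrid(icosphere(4), N = 64)
  rep <- uvGridDistortion(g)
  # global Q of the equirectangular sphere map is pi/2
  expect_lt(abs(rep@globalQ - pi / 2) / (pi / 2), 0.02)
  # per-pixel Q = 1/sin(v) away from the poles
  N <- 64
  vang <- seq(0, pi, length.out = N)
  Qm <- matrix(rep@Q, N)
  for (row in c(16, 32, 48))
    expect_lt(abs(median(Qm[row, ]) - 1 / sin(vang[row])), 0.05)
  # total differential area converges on the mesh area
  expect_lt(abs(sum(g@dA[, -ncol(g@dA)]) - surfaceArea(icosphere(4))) /
              surfaceArea(icosphere(4)), 0.02)

  # planar grid: conformal, uniform lambda
  gr <- expand.grid(v = 1:16, u = 1:16)
  S <- array(0, c(16, 16, 3))
  S[, , 1] <- matrix(gr$v, 16); S[, , 2] <- matrix(gr$u, 16)
  flat <- new("UVGrid", coords = S,
              faceIndex = matrix(1L, 16, 16),
              weights = array(rep(c(1, 0, 0), each = 256), c(16, 16, 3)),
              dA = computeUVdA(S, FALSE, periodicU = FALSE),
              rotation = diag(3),
              faces = rbind(c(1L, 2L, 3L)), seamDuplicated = FALSE)
  frep <- uvGridDistortion(flat, periodicU = FALSE)
  expect_equal(frep@globalQ, 1, tolerance = 1e-9)
  expect_lt(diff(range(frep@lambda)), 1e-9)
})

test_that("mesh comparison metrics behave on identical/translated/scaled", {
  m <- icosphere(2, radius = 10)
  same <- compareMeshes(m, m, projections = 10L, repeats = 2L,
                        volumeFromVoxels = FALSE)
  expect_equal(same@chamfer, 0)
  expect_equal(same@slicedW1, 0, tolerance = 1e-9)
  expect_equal(same@deltaAreaPct, 0)
  expect_equal(same@deltaVolumePct, 0)

  # wide flat grid translated by 3 along x: nearest vertex is the
  # pre-image (spacing 7 > 2 * 3), so CD is exactly 3 and the sliced-W1
  # translation oracle gives 3 as well
  gr <- expand.grid(x = seq(0, 70, by = 7), y = seq(0, 70, by = 7))
  plane <- SurfaceMesh(cbind(gr$x, gr$y, 0),
                       rbind(c(1L, 2L, 13L)), dropDegenerate = FALSE)
  shifted <- plane; shifted@vertices[, 1] <- plane@vertices[, 1] + 3
  md <- compareMeshes(plane, shifted, projections = 300L, repeats = 3L,
                      volumeFromVoxels = FALSE)
  expect_equal(md@chamfer, 3, tolerance = 1e-9)
  # max-sliced W1 of a rigid translation approaches the shift norm from
  # below as the projection count grows
  expect_lte(md@slicedW1, 3 + 1e-9)
  expect_gt(md@slicedW1, 3 * 0.95)

  # spheres 10 vs 11: analytic area difference
  s10 <- icosphere(3, 10); s11 <- icosphere(3, 11)
  md2 <- compareMeshes(s10, s11, projections = 10L, repeats = 2L,
                       volumeFromVoxels = FALSE)
  expect_lt(abs(md2@deltaAreaPct - 100 * (100 - 121) / 121), 0.5)

  # CD equals the brute-force nearest-neighbor oracle on small meshes
  a <- icosphere(2, 8); b <- icosphere(2, 9)
  b@vertices <- b@vertices + 1
  md3 <- compareMeshes(a, b, projections = 5L, repeats = 1L,
                       volumeFromVoxels = FALSE)
  expect_equal(md3@chamfer, chamferBrute(a@vertices, b@vertices),
               tolerance = 1e-10)
})
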