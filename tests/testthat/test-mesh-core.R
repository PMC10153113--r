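# Mesh data structures, FEM operators, voxelization, isosurfacing,
# remeshing, topology and scalar transfer.

test_that("mass and Laplacian operators match hand-assembled FEM values", {
  tri <- SurfaceMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0)),
                     rbind(1:3))
  ops <- buildOperators(tri)
  expect_equal(unname(diag(as.matrix(ops$mass))),
               rep((sqrt(3) / 4) / 3, 3), tolerance = 1e-12)
  expect_lt(max(abs(Matrix::rowSums(ops$laplacian))), 1e-10)

  # unit square split along the diagonal: two right angles oppose the
  # diagonal edge, so its cotangent weight vanishes
  sq <- SurfaceMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
                    rbind(c(1, 2, 3), c(1, 3, 4)))
  L <- buildOperators(sq)$laplacian
  expect_equal(L[1, 3], 0, tolerance = 1e-12)

  # mass trace = total area; Laplacian quadratic form one-signed
  fx <- icosphere(2, radius = 5)
  ops <- buildOperators(fx)
  expect_equal(sum(diag(as.matrix(ops$mass))), surfaceArea(fx),
               tolerance = 1e-8)
  set.seed(1)
  q <- replicate(10, {
    v <- rnorm(nVertices(fx))
    as.numeric(v %*% (ops$laplacian %*% v))
  })
  expect_true(all(q <= 1e-10))

  # degenerate face: cotangent errors, robust mollifies
  deg <- SurfaceMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(0, 1, 0)),
                     rbind(c(1, 2, 3), c(1, 2, 4)), dropDegenerate = FALSE)
  expect_error(buildOperators(deg, "cotangent"), "degenerate")
  expect_silent(buildOperators(deg, "robust"))
})

test_that("voxelization fills closed meshes with unbiased volume", {
  s <- icosphere(3, radius = 10, center = c(20, 20, 20))
  bv <- voxelize(s, dilationRadius = 1)
  expect_lt(abs(sum(bv@data) - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000),
            0.05)

  # a punched hole is healed by dilate/fill/erode
  holed <- punchDefects(s, nHoles = 1L, seed = 4)
  bh <- voxelize(holed, dilationRadius = 3)
  d <- dim(bh@data)
  lab <- cpp_cc3d(bh@data, d[1], d[2], d[3])
  expect_equal(max(lab), 1L)

  # r = 0: vertices stay within a voxel of the foreground boundary
  b0 <- voxelize(s, dilationRadius = 0)
  d <- dim(b0@data)
  inner <- array(cpp_edt3d(!b0@data, d[1], d[2], d[3]), d)
  boundary <- b0@data & inner <= 1
  bd <- array(cpp_edt3d(boundary, d[1], d[2], d[3]), d)
  pts <- round(sweep(s@vertices, 2, b0@origin))
  expect_lt(max(bd[pts]), 1 + 1e-9)

  expect_error(voxelize(SurfaceMesh(matrix(0, 0, 3),
                                    matrix(0L, 0, 3))), "empty")
})

test_that("isosurfacing and remeshing recover shape, topology, count", {
  m <- suppressMessages(meshFromVolume(ballVolume(10), remeshFraction = 0.5))
  top <- surfaceTopology(m)
  expect_true(top@watertight)
  expect_identical(top@genus, 0L)
  expect_lt(abs(surfaceArea(m) - 4 * pi * 100) / (4 * pi * 100), 0.1)

  tor <- suppressMessages(meshFromVolume(torusVolume(), remeshFraction = 0.4))
  expect_identical(surfaceTopology(tor)@genus, 1L)

  mt <- suppressMessages(meshFromVolume(ballVolume(10), remeshFraction = NULL))
  half <- suppressMessages(meshFromVolume(ballVolume(10),
                                          remeshFraction = 0.5))
  expect_lt(abs(nVertices(half) - 0.5 * nVertices(mt)) /
              (0.5 * nVertices(mt)), 0.1)
})

test_that("voxelize -> mesh round trip stays within 1.5 voxels Chamfer", {
  s <- icosphere(3, radius = 10, center = c(20, 20, 20))
  m <- suppressMessages(meshFromVolume(voxelize(s, dilationRadius = 1),
                                       remeshFraction = 0.5))
  md <- compareMeshes(m, s, projections = 10L, repeats = 2L,
                      volumeFromVoxels = FALSE)
  expect_lt(md@chamfer, 1.5)
})

test_that("topology reports match analytic and brute-force counts", {
  ico <- icosahedronMesh()
  top <- surfaceTopology(ico)
  expect_identical(c(top@nVertices, top@nEdges, top@nFaces),
                   c(12L, 30L, 20L))
  expect_identical(top@euler, 2L)
  expect_identical(top@genus, 0L)
  expect_true(top@watertight)

  expect_identical(surfaceTopology(torusMesh())@genus, 1L)

  tri <- SurfaceMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), rbind(1:3))
  ttop <- surfaceTopology(tri)
  expect_identical(ttop@boundaryLoops, 1L)
  expect_false(ttop@watertight)

  # brute-force edge map oracle on several fixtures
  for (m in list(ico, torusMesh(10L, 6L), icosphere(2))) {
    F <- faces(m)
    ek <- unique(paste(pmin(F[, 1], F[, 2]), pmax(F[, 1], F[, 2])))
    ek <- unique(c(ek, paste(pmin(F[, 2], F[, 3]), pmax(F[, 2], F[, 3])),
                   paste(pmin(F[, 3], F[, 1]), pmax(F[, 3], F[, 1]))))
    expect_identical(surfaceTopology(m)@nEdges, length(unique(ek)))
  }
})

test_that("scalar transfer is exact for identity, constant, linear", {
  src <- icosphere(3, radius = 10)
  dst <- icosphere(4, radius = 10)
  f <- src@vertices[, 1]
  expect_equal(transferScalars(src, src, f), f, tolerance = 1e-12)
  expect_equal(transferScalars(src, dst, rep(3, nVertices(src))),
               rep(3, nVertices(dst)), tolerance = 1e-12)
  # linear field: barycentric interpolation is exact up to the chordal
  # gap between the two sphere tessellations
  g <- transferScalars(src, dst, f)
  expect_lt(max(abs(g - dst@vertices[, 1])), meanEdgeLength(src))
  expect_error(transferScalars(src, dst, numeric(0)), "empty")
})
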