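# Reference-surface inference, affinity construction, binary/instance
# segmentation, disk unwrapping, watershed refinement, depth propagation
# and volumization.

test_that("the height image takes the top of the longest foreground run", {
  tb <- array(FALSE, c(60, 8, 8))
  tb[1:40, , ] <- TRUE
  expect_true(all(uvHeightImage(tb) == 40))
  tb2 <- array(FALSE, c(60, 4, 4))
  tb2[1:31, , ] <- TRUE
  tb2[51:56, 2, 2] <- TRUE
  h <- uvHeightImage(tb2)
  expect_identical(h[2, 2], 31)  # the longer run wins
  expect_error(uvHeightImage(array(FALSE, c(4, 4, 4))), "empty")
})

test_that("the ALS baseline passes under peaks and through flats", {
  expect_lt(max(abs(alsBaseline(matrix(3, 16, 16), downsample = 2) - 3)),
            1e-8)
  # symmetric unpenalized limit returns the input
  set.seed(1)
  img <- matrix(rnorm(256), 16, 16)
  out <- alsBaseline(img, p = 0.5, lambdaReg = 1e-9, iterations = 3,
                     downsample = 1)
  expect_lt(max(abs(out - img)), 1e-3 * diff(range(img)))
  # a narrow tall spike barely lifts the baseline
  plane <- matrix(2, 32, 32); plane[16, 16] <- 30
  bl <- alsBaseline(plane, p = 0.25, downsample = 2)
  expect_lt(abs(bl[16, 16] - 2) / 2, 0.30)
  expect_error(alsBaseline(plane, p = 1.2), "p must")
})

test_that("protrusion heights are depths relative to the baseline", {
  g <- gridMesh(8L, depth = 12)
  ph0 <- protrusionHeight(g, 0)
  expect_equal(ph0$h, rep(12, nVertices(g)))
  dref <- matrix(12, 8, 8)
  ph <- protrusionHeight(g, dref)
  expect_equal(ph$h, rep(0, nVertices(g)), tolerance = 1e-9)
})

test_that("affinity mixes distance and convexity kernels as stated", {
  ico <- icosahedronMesh()  # all edges equal
  Ad <- buildAffinity(ico, gamma = 1)
  offd <- Ad[1, 2]
  expect_equal(offd, exp(-1 / 2), tolerance = 1e-9)
  expect_equal(Matrix::diag(Ad), rep(1, 12))
  expect_true(Matrix::isSymmetric(Ad))
  # coplanar neighbors have unit convexity affinity
  flat <- gridMesh(5L, depth = 0)
  Ac <- buildAffinity(flat, gamma = 0)
  E <- topomesh:::meshEdges(flat@faces)$edges
  inner <- E[E[, 1] == 13 & E[, 2] == 14, , drop = FALSE]
  expect_equal(Ac[13, 14], 1, tolerance = 1e-9)
})

test_that("binary segmentation covers planted caps and stays local", {
  sb <- segBundle()
  b <- sb$bundle
  bs <- b$binaryLabels
  tt <- transferScalars(sb$fx$mesh, b$segMeshCartesian,
                        as.numeric(sb$fx$truth), method = "nearest")
  for (l in 1:10) expect_gt(mean(bs[tt == l]), 0.9)

  # flat surface: empty with a warning
  h <- rep(0.1, 100)
  A <- Matrix::Diagonal(100) + Matrix::bandSparse(100, k = 1, symmetric = TRUE)
  expect_warning(out <- binarySegment(h, A, rep(1, 100)), "flat")
  expect_identical(out, integer(100))

  # operation-level locality and the seed-area filter: two hills on a
  # large flat sheet; the small hill is filtered, diffusion from the big
  # hill never reaches the far corner
  n <- 100L
  gr <- expand.grid(v = seq_len(n), u = seq_len(n))
  hills <- 20 * exp(-((gr$v - 30)^2 + (gr$u - 30)^2) / (2 * 9^2)) +
    20 * exp(-((gr$v - 75)^2 + (gr$u - 75)^2) / (2 * 3^2))
  sheet <- gridMesh(n, depth = 0)
  sheet@vertices[, 1] <- hills
  Ag <- buildAffinity(sheet, 0.9)
  bsg <- binarySegment(hills, Ag, rep(1, n * n))
  at <- function(v, u) bsg[(u - 1L) * n + v]
  expect_identical(at(30L, 30L), 1L)   # big hill segmented
  expect_identical(at(75L, 75L), 0L)   # small hill removed by the filter
  expect_identical(at(97L, 97L), 0L)   # far corner untouched
})

test_that("instance segmentation finds each planted protrusion once", {
  sb <- segBundle()
  # well-separated caps: exactly one label per cap
  octa <- memo("twelveBundle", {
    fx6 <- makeFixture(fixtureSpec(baseRadius = 32, motif = "bleb",
                                   k = 12L, width = 0.18, seed = 112L))
    b6 <- suppressWarnings(suppressMessages(
      runPipeline(fx6$mesh, sb$cfg, fastReference = TRUE,
                  reconstruct = FALSE)))
    list(fx = fx6, b = b6)
  })
  inst <- octa$b$instanceLabels
  expect_identical(max(inst), 12L)
  tt <- transferScalars(octa$fx$mesh, octa$b$segMeshCartesian,
                        as.numeric(octa$fx$truth), method = "nearest")
  hit <- vapply(seq_len(max(inst)), function(l) {
    w <- inst == l & tt > 0
    if (!any(w)) return(0L)
    as.integer(names(which.max(table(tt[w]))))
  }, integer(1))
  expect_identical(sort(hit), 1:12)

  # a smooth ball yields no instances
  ball <- memo("smoothBall", {
    fx0 <- makeFixture(fixtureSpec(baseRadius = 32, motif = "bleb", k = 0,
                                   seed = 2))
    suppressWarnings(suppressMessages(
      runPipeline(fx0$mesh, sb$cfg, fastReference = TRUE,
                  reconstruct = FALSE)))
  })
  expect_identical(max(ball$instanceLabels), 0L)
})

test_that("close curvature-separated bumps keep distinct labels", {
  # two hills whose footprints nearly touch (valley narrower than the
  # 3-voxel label expansion): the curvature valley separates the seeds
  D <- 40L; n <- 64L
  gr <- expand.grid(v = seq_len(n), u = seq_len(n))
  hgt <- 10 + 14 * exp(-((gr$v - 32)^2 + (gr$u - 25)^2) / (2 * 5^2)) +
    14 * exp(-((gr$v - 32)^2 + (gr$u - 40)^2) / (2 * 5^2))
  tb <- array(FALSE, c(D, n, n))
  for (i in seq_len(n * n))
    tb[seq_len(min(D, round(hgt[i]))), gr$v[i], gr$u[i]] <- TRUE
  phiT <- array(cpp_edt3d(!tb, D, n, n) - cpp_edt3d(tb, D, n, n),
                c(D, n, n))
  phiT <- array(cpp_gauss3d(as.numeric(phiT), D, n, n, 1), c(D, n, n))
  Ht <- topomesh:::divergenceMeanCurvature(phiT)
  mesh <- gridMesh(n, depth = 0)
  mesh@vertices[, 1] <- hgt
  A <- buildAffinity(mesh, 0.9)
  inst <- instanceSegment(Ht, tb, "bleb_filopodia",
                          rep(1L, n * n), A, mesh, rep(1, n * n),
                          minComponentVoxels = 60L, minLabelArea = 12,
                          poleMargin = 0L, seed = 3L)
  expect_identical(max(inst), 2L)
  # the two labels sit on opposite sides of the valley
  lab1u <- mean(mesh@vertices[inst == 1L, 3])
  lab2u <- mean(mesh@vertices[inst == 2L, 3])
  expect_gt(abs(lab1u - lab2u), 8)
})

test_that("open protrusion submeshes unwrap to the square", {
  # the elliptical mapping sends the disk point (1,0) to the square edge
  expect_equal(topomesh:::diskToSquare(cbind(1, 0)),
               cbind(1, 0), tolerance = 1e-12)
  expect_equal(topomesh:::diskToSquare(cbind(0, -1)),
               cbind(0, -1), tolerance = 1e-12)

  # a flat disk with an exactly circular boundary maps to the unit disk
  # as the identity up to a similarity
  dm <- ringDiskMesh(6L)
  sqc <- unwrapProtrusion(dm, N = 32, relaxIterations = 0L)
  V2 <- cbind(sqc$disk2D, 0)
  rep <- faceDistortion(dm, SurfaceMesh(V2, sqc$faces,
                                        dropDegenerate = FALSE))
  expect_lt(rep@globalQ - 1, 1e-3)

  # a hemisphere unwraps fold-free with bounded area distortion
  hs <- icosphere(4)
  keepH <- which(apply(matrix(hs@vertices[hs@faces, 3], ncol = 3), 1,
                       min) > 0)
  hemi <- submeshByFaces(hs, keepH)$mesh
  sqh <- unwrapProtrusion(hemi, N = 64)
  expect_lte(sqh$lambdaGlobal, 1.1)
  # no flipped 2D faces
  xy <- sqh$vertex2D
  F <- sqh$faces
  sa <- (xy[F[, 2], 1] - xy[F[, 1], 1]) * (xy[F[, 3], 2] - xy[F[, 1], 2]) -
    (xy[F[, 2], 2] - xy[F[, 1], 2]) * (xy[F[, 3], 1] - xy[F[, 1], 1])
  expect_true(all(sa > 0) || all(sa < 0))
  # closed or multi-boundary surfaces are rejected
  expect_error(unwrapProtrusion(icosphere(2)), "one boundary")
})

test_that("gradient watershed splits conjoined blebs", {
  mb <- mergedBlebFixture()
  merged <- as.integer(mb$truth > 0)
  ref <- refineSplitBlebs(mb$mesh, merged, mb$H)
  expect_identical(max(ref), 2L)
  # a single clean bleb passes through unchanged in count
  single <- ifelse(mb$d2 > 0.5, 0L, as.integer(mb$d1 > 0.5))
  refS <- refineSplitBlebs(mb$mesh, single, mb$H)
  expect_identical(max(refS), 1L)
  # refinement improves agreement with the planted pair
  lab0 <- merged
  expect_gte(nmi(ref, mb$truth), nmi(lab0, mb$truth))
})

test_that("harmonic inpainting imputes protrusion footprints", {
  img <- matrix(5, 10, 10)
  expect_identical(inpaintReference(img, matrix(FALSE, 10, 10)), img)
  msk <- matrix(FALSE, 10, 10); msk[5, 5] <- TRUE
  expect_equal(inpaintReference(img, msk)[5, 5], 5, tolerance = 1e-9)
  ramp <- matrix(rep(seq(0, 9, length.out = 20), each = 20), 20, 20)
  mskD <- matrix(FALSE, 20, 20); mskD[8:12, 8:12] <- TRUE
  err <- max(abs(inpaintReference(ramp, mskD)[mskD] - ramp[mskD]))
  expect_lt(err, 0.1 * diff(range(ramp)))
  expect_error(inpaintReference(img, matrix(TRUE, 10, 10)), "fully")
})

test_that("depth propagation conserves labels without lateral leakage", {
  cf <- columnFixture()
  lab <- propagateLabelsDepth(cf$tb, cf$mesh, cf$labels)
  expect_identical(sort(unique(as.integer(lab[lab > 0]))), c(1L, 2L))
  gg <- expand.grid(d = 11:25, v = 1:48, u = 1:48)
  col1 <- lab[cbind(gg$d, gg$v, gg$u)][(gg$v - 16)^2 + (gg$u - 16)^2 <= 9]
  col2 <- lab[cbind(gg$d, gg$v, gg$u)][(gg$v - 16)^2 + (gg$u - 34)^2 <= 9]
  expect_true(all(col1 == 1L))
  expect_true(all(col2 == 2L))
  # every foreground voxel is labeled
  expect_true(all(lab[cf$tb] > 0L))
})

test_that("volumization measures protrusion volumes above the cortex", {
  cf <- columnFixture()
  lab <- propagateLabelsDepth(cf$tb, cf$mesh, cf$labels)
  refbin <- array(FALSE, dim(cf$tb)); refbin[1:10, , ] <- TRUE
  vz <- volumizeProtrusions(lab, refbin, meshes = TRUE)
  expect_identical(nrow(vz$table), 2L)
  ana <- pi * 16 * 15
  expect_true(all(abs(vz$table$volume - ana) / ana < 0.15))
  # partition: protrusions + cortex account for the full foreground
  expect_identical(sum(vz$labels > 0L) + sum(refbin & cf$tb),
                   sum(cf$tb))
  expect_length(vz$meshes, 2L)
  for (m in vz$meshes) expect_true(surfaceTopology(m)@watertight)
})

test_that("fixture generation is seeded, labeled and defect-capable", {
  s0 <- makeFixture(fixtureSpec(k = 0L, seed = 5))
  expect_identical(unique(s0$truth), 0L)
  a <- makeFixture(fixtureSpec(k = 12L, seed = 11))
  b <- makeFixture(fixtureSpec(k = 12L, seed = 11))
  expect_identical(a$mesh@vertices, b$mesh@vertices)
  expect_identical(sort(unique(a$truth)), 0:12)
  pd <- punchDefects(a$mesh, nHoles = 1L, nHandles = 1L, seed = 2)
  top <- surfaceTopology(pd)
  expect_identical(top@boundaryLoops, 1L)
  expect_identical(top@genus, 1L)
  expect_false(top@watertight)
  # the defected mesh still yields a genus-0 reference through the
  # smoothing + voxelize + remesh route
  fl <- runCMCF(pd, flowConfig(dt = 5e-4, maxIterations = 12,
                               deltaThresh = 0.05), stopEarly = TRUE)
  ref0 <- flowSnapshot(fl, autoStopIndex(fl, 0.05))
  bv <- voxelize(ref0, dilationRadius = 5)
  ref <- suppressMessages(meshFromVolume(bv, remeshFraction = 0.1))
  expect_identical(surfaceTopology(ref)@genus, 0L)
})
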