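# Signed distance, topographic space construction, resampling,
# topographic meshing and the Cartesian back-map.

test_that("signed distance is positive inside and zero at the surface", {
  bv <- ballVolume(10, 32)
  sdf <- signedDistance(bv)
  ctr <- round((32 + 1) / 2)
  expect_lt(abs(sdf@data[ctr, ctr, ctr] - 10), 1)
  expect_lt(abs(sdf@data[ctr, ctr, 32] - (-(32 - ctr - 10))), 1.2)
  # |phi| = 0 contour within a voxel of the analytic surface
  # the sign change lives between voxel centers, so the innermost
  # one-voxel bands on both sides bracket the analytic surface
  near <- abs(sdf@data) <= 1
  g <- which(near, arr.ind = TRUE)
  expect_gt(nrow(g), 100)
  r <- sqrt(rowSums(sweep(g, 2, rep((32 + 1) / 2, 3))^2))
  expect_lt(max(abs(r - 10)), 1.5)
  expect_error(signedDistance(BinaryVolume(array(TRUE, c(3, 3, 3)))),
               "outside")
})

test_that("shells advance at alpha voxels per depth step on a ball", {
  bs <- memo("ballSpace", ballSpace())
  space <- bs$space
  for (dd in c(-10, -4, 0, 4, 10)) {
    shell <- matrix(space@coords[space@dIn + 1 + dd, , , ], ncol = 3)
    r <- sqrt(rowSums(sweep(shell, 2, rep(24, 3))^2))
    expect_lt(max(abs(r - (14 + 0.5 * dd))), 0.5)
  }
  # alpha = 0: every shell equals the d = 0 shell
  s0 <- ballSpace(alpha = 0, dIn = 3L, dOut = 3L, N = 32)$space
  base <- s0@coords[4, , , ]
  for (k in 1:7) expect_equal(s0@coords[k, , , ], base, tolerance = 1e-9)
})

test_that("automatic outward expansion encloses the planted protrusions", {
  sb <- segBundle()
  space <- sb$bundle$space
  tb <- sb$bundle$topoBinary
  # the outermost slice must be clear of foreground while the bump tips
  # reach close below the top of the depth domain
  expect_false(any(tb[dim(tb)[1], , ]))
  top <- max(which(apply(tb, 1, any)))
  expect_gte(top, dim(tb)[1] - 10L)
})

test_that("volume resampling respects symmetry and containment", {
  bs <- memo("ballSpace", ballSpace())
  # constant volume resamples to the constant
  cst <- array(2.5, dim(bs$bv@data))
  tc <- resampleVolume(bs$space, cst, origin = bs$bv@origin)
  expect_equal(range(tc), c(2.5, 2.5), tolerance = 1e-9)
  # radially symmetric intensity: each d-slice is near-constant
  d <- dim(bs$bv@data)
  g <- expand.grid(x = 1:d[1], y = 1:d[2], z = 1:d[3])
  ctr <- 24 - bs$bv@origin
  I <- array(sqrt((g$x - ctr[1])^2 + (g$y - ctr[2])^2 +
                    (g$z - ctr[3])^2), d)
  tI <- resampleVolume(bs$space, I, origin = c(0, 0, 0))
  for (k in c(3, 11, 18))
    expect_lt(stats::sd(tI[k, 3:126, ]), 0.35)
  # cell binary: the d = 0 slice of a reference inside the cell is all
  # foreground
  cell <- icosphere(3, radius = 17, center = rep(24, 3))
  cb <- voxelize(cell, dilationRadius = 1, pad = 6)
  tB <- resampleVolume(bs$space, cb)
  expect_true(all(tB[bs$space@dIn + 1, , ] > 0.5))
})

test_that("topographic meshing flattens a ball and counts planted bumps", {
  bs <- memo("ballSpace", ballSpace())
  cell <- icosphere(3, radius = 17, center = rep(24, 3))
  cb <- voxelize(cell, dilationRadius = 1, pad = 6)
  tb <- resampleVolume(bs$space, cb) > 0.5
  tm <- suppressMessages(topographicMesh(tb, remeshFraction = 0.3,
                                         closeBottom = FALSE))
  # a ball over a concentric ball reference is a constant-depth terrain
  # (away from the domain-cut walls at the image borders)
  terr <- tm@vertices[, 1] > 3 &
    tm@vertices[, 2] > 4 & tm@vertices[, 2] < 124 &
    tm@vertices[, 3] > 4 & tm@vertices[, 3] < 253
  expect_lt(stats::sd(tm@vertices[terr, 1]), 1)
  expect_gte(median(radiusRatio(tm)), 0.7)

  # one topographic hill per planted bump (u-periodic component count)
  sb <- segBundle()
  him <- uvHeightImage(sb$bundle$topoBinary)
  dref <- alsBaseline(him, downsample = 4L)
  lab <- EBImage::bwlabel((him - dref) > 6)
  # drop speck artifacts; hills are tens of pixels
  specks <- which(tabulate(lab[lab > 0L]) < 10L)
  lab[lab %in% specks] <- 0L
  ids <- setdiff(unique(as.integer(lab)), 0L)
  seamPairs <- unique(cbind(lab[, 1], lab[, ncol(lab)]))
  seamPairs <- seamPairs[seamPairs[, 1] > 0 & seamPairs[, 2] > 0 &
                           seamPairs[, 1] != seamPairs[, 2], ,
                         drop = FALSE]
  expect_identical(length(ids) - nrow(seamPairs), 10L)
})

test_that("the Cartesian back-map inverts the topographic construction", {
  bs <- memo("ballSpace", ballSpace())
  space <- bs$space
  # d = 0 shell maps to the UV grid coordinates exactly
  N <- dim(space@coords)[2]; M <- dim(space@coords)[3]
  pts <- cbind(space@dIn + 1, rep(seq_len(N), 4),
               rep(c(2, 60, 130, 220), each = N))
  mapped <- topoToCartesian(space, pts)
  truth <- t(vapply(seq_len(nrow(pts)), function(i)
    space@coords[pts[i, 1], pts[i, 2], pts[i, 3], ], numeric(3)))
  expect_equal(mapped, truth, tolerance = 1e-9)

  # ball round trip: the reconstructed terrain sheet stays within 1.5
  # voxels of the input surface
  cell <- icosphere(3, radius = 17, center = rep(24, 3))
  cb <- voxelize(cell, dilationRadius = 1, pad = 6)
  tb <- resampleVolume(bs$space, cb) > 0.5
  tm <- suppressMessages(topographicMesh(tb, remeshFraction = 0.3,
                                         closeBottom = FALSE))
  stopo <- suppressWarnings(topoToCartesian(space, tm))
  md <- compareMeshes(stopo, cell, projections = 5L, repeats = 1L,
                      volumeFromVoxels = FALSE)
  expect_lt(md@chamfer, 1.5)
  # strict mode rejects out-of-domain coordinates
  expect_error(topoToCartesian(space, cbind(-3, 1, 1), strict = TRUE),
               "out of")
})

test_that("depth is monotone and the volume element accounts for counts", {
  bs <- memo("ballSpace", ballSpace())
  space <- bs$space
  # along every (u,v) ray the Cartesian distance to the d=0 shell grows
  # with |d|
  base <- space@coords[space@dIn + 1, , , ]
  for (sgn in c(-1, 1)) {
    prev <- array(0, dim(base)[1:2])
    for (k in 1:8) {
      sh <- space@coords[space@dIn + 1 + sgn * k, , , ]
      dist <- sqrt(apply((sh - base)^2, c(1, 2), sum))
      expect_gte(min(dist - prev), -0.15)
      prev <- dist
    }
  }
  # dV-corrected topographic foreground matches the Cartesian count over
  # the region the depth domain covers (the cell core below the
  # innermost shell is outside the (d,u,v) domain by construction)
  cell <- icosphere(3, radius = 17, center = rep(24, 3))
  cb <- voxelize(cell, dilationRadius = 1, pad = 6)
  tb <- resampleVolume(bs$space, cb) > 0.5
  dV <- topomesh:::topographicDV(space)
  sh1 <- matrix(space@coords[1, , , ], ncol = 3)
  rIn <- mean(sqrt(rowSums(sweep(sh1, 2, rep(24, 3))^2))) - space@alpha / 2
  gg <- which(cb@data, arr.ind = TRUE)
  rv <- sqrt(rowSums(sweep(sweep(gg, 2, -cb@origin), 2, rep(24, 3))^2))
  covered <- sum(rv >= rIn)
  expect_lt(abs(sum(dV[tb]) - covered) / covered, 0.10)
})
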