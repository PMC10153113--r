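# Quasi-conformal spherical parameterization and equiareal relaxation.

test_that("a unit icosphere maps to itself up to symmetry", {
  ico <- icosphere(3)
  sp <- sphericalParameterize(ico, maxIterations = 100)
  expect_equal(sp@history$globalQ[1], 1, tolerance = 1e-3)
  expect_lt(max(abs(sqrt(rowSums(sp@sphere@vertices^2)) - 1)), 1e-9)
})

test_that("bumpy genus-0 surfaces parameterize fold-free and conformal", {
  sp <- directParam()  # direct parameterization of the 20-bump input
  V <- sp@sphere@vertices
  expect_identical(countFlippedSphereFaces(V, sp@sphere@faces), 0L)
  expect_lte(sp@history$globalQ[1], 1.05)
  expect_error(sphericalParameterize(torusMesh()), "genus")
})

test_that("relaxation reaches the equiareal optimum without folding", {
  sp <- distortedParam()$sp
  rel <- relaxedDistorted()
  hist <- relaxationHistory(rel)
  final <- hist[nrow(hist), ]
  expect_lt(abs(final$medianLambda - 1), 0.01)
  expect_lte(nrow(hist) - 1, 50)
  # bijectivity: no flipped spherical triangle at any accepted iteration
  expect_identical(countFlippedSphereFaces(rel@sphere@vertices,
                                           rel@sphere@faces), 0L)
  # trade-off monotonicity (5% jitter): lambda spread shrinks while the
  # conformal error grows
  expect_true(all(diff(hist$iqrLambda) <= 0.05 * hist$iqrLambda[1] + 1e-9))
  expect_true(all(diff(hist$globalQ) >= -0.05 * hist$globalQ[1]))

  # an already-equiareal parameterization barely moves
  ico <- icosphere(3)
  spI <- sphericalParameterize(ico, maxIterations = 50)
  relI <- relaxAreaDistortion(spI, maxIterations = 2L)
  expect_lt(max(abs(relI@sphere@vertices - spI@sphere@vertices)), 0.02)
})

test_that("stopping criteria pick the documented iterations", {
  rel <- relaxedDistorted()
  hist <- relaxationHistory(rel)
  tOmega <- evaluateStopCriterion(hist, "equiareal")
  expect_gt(tOmega, 0)
  expect_identical(evaluateStopCriterion(hist, "conformal_mips"), 0L)
  # the joint conformal/area optimum sits strictly inside (0, tOmega)
  tIso <- evaluateStopCriterion(hist, "isometric_sum")
  expect_gt(tIso, 0)
  expect_lt(tIso, tOmega)
  tAm <- evaluateStopCriterion(hist, "area_mips")
  expect_gt(tAm, 0)
  expect_lte(tAm, tOmega)
  # constant-lambda history: the isometric argmin is the Q argmin
  h2 <- data.frame(iteration = 0:3, medianLambda = 1,
                   iqrLambda = 0, globalQ = c(1.5, 1.2, 1.4, 1.6),
                   mips = 0, areaMips = 0,
                   isometric = 0.5 * c(1.5, 1.2, 1.4, 1.6))
  expect_identical(evaluateStopCriterion(h2, "isometric_sum"), 1L)
  expect_error(evaluateStopCriterion(hist, "nope"))
})

test_that("direct genus-0 unwrapping resamples the input surface", {
  pf <- paramFixture()
  spDirect <- directParam()
  # the direct path pulls the input surface itself through the (u,v)
  # grid; its lookup cloud must stay on the input surface
  gD <- buildUVGrid(spDirect, target = pf$fx$mesh, N = 64)
  cloudD <- SurfaceMesh(matrix(gD@coords, ncol = 3),
                        rbind(c(1L, 2L, 3L)), dropDegenerate = FALSE)
  md <- compareMeshes(cloudD, pf$fx$mesh, projections = 5L, repeats = 1L,
                      volumeFromVoxels = FALSE)
  expect_lt(md@chamfer, 2)
})
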