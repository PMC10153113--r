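# Shared fixtures, memoized across test files (expensive pipeline stages
# are computed once per test session).

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# icosahedron: V=12, E=30, F=20
icosahedronMesh <- function() icosphere(0L)

# triangulated torus (nu x nv grid, major R, minor r)
torusMesh <- function(nu = 24L, nv = 12L, R = 10, r = 4) {
  iu <- rep(seq_len(nu), nv); iv <- rep(seq_len(nv), each = nu)
  a <- 2 * pi * (iu - 1) / nu; b <- 2 * pi * (iv - 1) / nv
  V <- cbind((R + r * cos(b)) * cos(a), (R + r * cos(b)) * sin(a),
             r * sin(b))
  id <- function(i, j) ((j - 1) %% nv) * nu + ((i - 1) %% nu) + 1
  F <- NULL
  for (j in seq_len(nv)) for (i in seq_len(nu)) {
    F <- rbind(F, c(id(i, j), id(i + 1, j), id(i, j + 1)),
               c(id(i + 1, j), id(i + 1, j + 1), id(i, j + 1)))
  }
  SurfaceMesh(V, F)
}

# planar grid mesh over [1..n]^2 at constant depth
gridMesh <- function(n = 12L, depth = 5, representation = "topographic") {
  gr <- expand.grid(v = seq_len(n), u = seq_len(n))
  idx <- matrix(seq_len(n * n), n, n)
  F <- NULL
  for (i in seq_len(n - 1)) for (j in seq_len(n - 1)) {
    F <- rbind(F, c(idx[i, j], idx[i + 1, j], idx[i, j + 1]),
               c(idx[i + 1, j], idx[i + 1, j + 1], idx[i, j + 1]))
  }
  SurfaceMesh(cbind(depth, gr$v, gr$u), F, representation = representation)
}

# solid ball binary volume
ballVolume <- function(R = 10, n = 2 * R + 12) {
  ctr <- (n + 1) / 2
  g <- expand.grid(x = seq_len(n), y = seq_len(n), z = seq_len(n))
  fg <- array(sqrt((g$x - ctr)^2 + (g$y - ctr)^2 + (g$z - ctr)^2) <= R,
              c(n, n, n))
  BinaryVolume(fg)
}

# solid torus binary volume
torusVolume <- function(R = 12, r = 5, n = 2 * (R + r) + 10) {
  ctr <- (n + 1) / 2
  g <- expand.grid(x = seq_len(n), y = seq_len(n), z = seq_len(n))
  rho <- sqrt((g$x - ctr)^2 + (g$y - ctr)^2)
  fg <- array((rho - R)^2 + (g$z - ctr)^2 <= r^2, c(n, n, n))
  BinaryVolume(fg)
}

# the spherical-parameterization validation fixture: Gaussian bumps
# (R = 32, 20 bumps, amplitude 0.2R), flowed, remeshed, parameterized
paramFixture <- function() memo("paramFixture", {
  fx <- makeFixture(fixtureSpec(baseRadius = 32, motif = "gauss", k = 20,
                                amplitude = 0.2, width = 0.15, seed = 7))
  fl <- runCMCF(fx$mesh, flowConfig(dt = 5e-4, maxIterations = 50,
                                    deltaThresh = 0.05), stopEarly = TRUE)
  st <- autoStopIndex(fl, 0.05)
  ref0 <- flowSnapshot(fl, st)
  bv <- voxelize(ref0, dilationRadius = 5)
  mt <- suppressMessages(meshFromVolume(bv, remeshFraction = NULL))
  ref <- remeshUniform(mt, 6000L)
  ref@representation <- "reference"
  sp <- sphericalParameterize(ref)
  list(fx = fx, ref = ref, sp = sp)
})

# the same fixture relaxed to the equiareal optimum
relaxedFixture <- function() memo("relaxedFixture", {
  relaxAreaDistortion(paramFixture()$sp)
})

# direct spherical parameterization of the bumpy input itself (strong
# area distortion; exercises the relaxation)
directParam <- function() memo("directParam", {
  fx <- paramFixture()$fx
  sphericalParameterize(fx$mesh, dt = 0.05, maxIterations = 250)
})

# full pipeline bundle on a cap-bleb fixture (segmentation study scale)
segBundle <- function() memo("segBundle", {
  cfg <- scaleSegmentationFilters(
    pipelineConfig(uvN = 128L, dIn = 10L, cmcfTmin = 8L, sphereDt = 0.1,
                   sphereMaxIterations = 200L, seed = 1L),
    voxelSize = 0.3)
  fx <- makeFixture(fixtureSpec(baseRadius = 32, motif = "bleb", k = 10,
                                width = 0.18, seed = 77))
  b <- suppressWarnings(suppressMessages(
    runPipeline(fx$mesh, cfg, fastReference = TRUE, reconstruct = FALSE)))
  list(fx = fx, bundle = b, cfg = cfg)
})

# brute-force nearest-neighbor chamfer oracle
chamferBrute <- function(V1, V2) {
  d12 <- apply(V1, 1, function(p)
    sqrt(min(colSums((t(V2) - p)^2))))
  d21 <- apply(V2, 1, function(p)
    sqrt(min(colSums((t(V1) - p)^2))))
  0.5 * (mean(d12) + mean(d21))
}

# normalized mutual information of two labelings (sqrt normalization)
nmi <- function(a, b) {
  tab <- table(a, b)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  ind <- p > 0
  mi <- sum(p[ind] * log(p[ind] / outer(px, py)[ind]))
  hx <- -sum(px[px > 0] * log(px[px > 0]))
  hy <- -sum(py[py > 0] * log(py[py > 0]))
  if (hx == 0 || hy == 0) return(0)
  mi / sqrt(hx * hy)
}

# ball-reference topographic space shared by topography/acceptance tests
ballSpace <- function(alpha = 0.5, dIn = 10L, dOut = 10L, N = 128) {
  ball <- icosphere(3, radius = 14, center = rep(24, 3))
  bv <- voxelize(ball, dilationRadius = 1, pad = 9)
  sdf <- signedDistance(bv)
  g <- buildUVGrid(icosphere(3), target = ball, N = N)
  list(space = buildTopographicSpace(g, sdf, alpha = alpha, dIn = dIn,
                                     dOut = dOut),
       ball = ball, bv = bv, uv = g)
}

# slab with two labeled columns (depth propagation / volumization)
columnFixture <- function() {
  D <- 30L; Nv <- 48L; Nu <- 48L
  tb <- array(FALSE, c(D, Nv, Nu))
  tb[1:10, , ] <- TRUE
  gg <- expand.grid(v = seq_len(Nv), u = seq_len(Nu))
  for (cc in list(c(16, 16), c(16, 34))) {
    sel <- (gg$v - cc[1])^2 + (gg$u - cc[2])^2 <= 16
    for (d in 11:25) tb[cbind(d, gg$v[sel], gg$u[sel])] <- TRUE
  }
  set.seed(4)
  V <- rbind(cbind(25, 16 + runif(20, -3, 3), 16 + runif(20, -3, 3)),
             cbind(25, 16 + runif(20, -3, 3), 34 + runif(20, -3, 3)))
  tmf <- SurfaceMesh(V, cbind(1:38, 2:39, 3:40),
                     representation = "topographic",
                     dropDegenerate = FALSE)
  list(tb = tb, mesh = tmf, labels = c(rep(1L, 20), rep(2L, 20)))
}

# two overlapping hemispherical blebs merged into one label
mergedBlebFixture <- function() memo("mergedBleb", {
  set.seed(2)
  m <- icosphere(5, radius = 32, center = rep(48, 3))
  P <- sweep(m@vertices, 2, rep(48, 3))
  Pn <- P / sqrt(rowSums(P^2))
  th <- 0.25
  c1 <- c(1, 0, 0)
  c2 <- c(cos(1.5 * th), sin(1.5 * th), 0); c2 <- c2 / sqrt(sum(c2^2))
  disp <- function(cdir) {
    t <- acos(pmin(1, pmax(-1, Pn %*% cdir)))
    8 * sqrt(pmax(0, 1 - (t / th)^2))
  }
  d1 <- disp(c1); d2 <- disp(c2)
  mm <- SurfaceMesh(sweep(Pn * as.numeric(32 + pmax(d1, d2)), 2,
                          rep(48, 3), `+`), m@faces)
  list(mesh = mm, d1 = d1, d2 = d2,
       H = meanCurvatureSDF(mm),
       truth = ifelse(d1 >= d2 & d1 > 0.5, 1L,
                      ifelse(d2 > 0.5, 2L, 0L)))
})

# strongly area-distorting direct parameterization (tall wide bumps):
# relaxation needs several iterations, exposing the stopping criteria
distortedParam <- function() memo("distortedParam", {
  fx <- makeFixture(fixtureSpec(baseRadius = 32, motif = "gauss", k = 12,
                                amplitude = 0.35, width = 0.2, seed = 21,
                                subdivisions = 5L))
  list(fx = fx,
       sp = sphericalParameterize(fx$mesh, dt = 0.1,
                                  maxIterations = 200))
})

relaxedDistorted <- function() memo("relaxedDistorted", {
  relaxAreaDistortion(distortedParam()$sp)
})

# flat unit disk with an exactly circular boundary (concentric rings,
# two-pointer stitching between rings of 6k vertices)
ringDiskMesh <- function(K = 6L) {
  V <- rbind(c(0, 0, 0))
  ringIdx <- list(1L)
  for (k in seq_len(K)) {
    n <- 6L * k
    ang <- 2 * pi * (seq_len(n) - 1L) / n
    ringIdx[[k + 1L]] <- nrow(V) + seq_len(n)
    V <- rbind(V, cbind(cos(ang), sin(ang), 0) * (k / K))
  }
  F <- NULL
  for (k in seq_len(K)) {
    inner <- ringIdx[[k]]; outer <- ringIdx[[k + 1L]]
    aiE <- c(2 * pi * (seq_along(inner) - 1L) / length(inner), 2 * pi)
    aoE <- c(2 * pi * (seq_along(outer) - 1L) / length(outer), 2 * pi)
    inE <- c(inner, inner[1L]); ouE <- c(outer, outer[1L])
    i <- 1L; o <- 1L
    while (i < length(inE) || o < length(ouE)) {
      if (o < length(ouE) &&
          (i == length(inE) || aoE[o + 1L] <= aiE[i + 1L])) {
        F <- rbind(F, c(inE[i], ouE[o], ouE[o + 1L]))
        o <- o + 1L
      } else {
        if (inE[i] != inE[i + 1L])
          F <- rbind(F, c(inE[i], ouE[o], inE[i + 1L]))
        i <- i + 1L
      }
    }
  }
  SurfaceMesh(V, F, dropDegenerate = FALSE)
}
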