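# Curvature, distortion and mesh-comparison metrics.

#' Per-face radius-ratio quality
#'
#' Twice the ratio of inradius to circumradius; 1 for an equilateral
#' triangle, approaching 0 for needle triangles, 0 for degenerate faces.
#'
#' @param mesh \linkS4class{SurfaceMesh}.
#' @return numeric vector in [0, 1], one entry per face.
#' @export
radiusRatio <- function(mesh) {
  V <- mesh@vertices; F <- mesh@faces
  a <- sqrt(rowSums((V[F[, 2], , drop = FALSE] - V[F[, 3], , drop = FALSE])^2))
  b <- sqrt(rowSums((V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE])^2))
  cc <- sqrt(rowSums((V[F[, 1], , drop = FALSE] - V[F[, 2], , drop = FALSE])^2))
  s <- (a + b + cc) / 2
  area2 <- s * (s - a) * (s - b) * (s - cc)
  area <- sqrt(pmax(area2, 0))
  out <- 8 * area^2 / (s * a * b * cc)
  out[!is.finite(out)] <- 0
  pmin(pmax(out, 0), 1)
}

#' Discrete Gaussian curvature (angle deficit)
#'
#' \code{K_v = 2*pi - sum of incident interior angles}. Defined for closed
#' manifold meshes only; by Gauss-Bonnet the deficits sum to
#' \code{2*pi*chi}.
#'
#' @param mesh closed \linkS4class{SurfaceMesh}.
#' @param normalizeByArea divide by the barycentric vertex area to obtain
#'   a pointwise curvature (voxel^-2).
#' @return per-vertex numeric vector.
#' @export
gaussianCurvature <- function(mesh, normalizeByArea = FALSE) {
  top <- surfaceTopology(mesh)
  if (top@boundaryLoops > 0L)
    stop("Gaussian curvature by angle deficit requires a closed mesh")
  V <- mesh@vertices; F <- mesh@faces
  ang <- interiorAngles(V, F)
  n <- nrow(V)
  tot <- numeric(n)
  for (c in 1:3) tot <- tot + tapplySum(ang[, c], F[, c], n)
  K <- 2 * pi - tot
  if (normalizeByArea) {
    a <- triangleAreas(V, F)
    va <- numeric(n)
    for (c in 1:3) va <- va + tapplySum(a / 3, F[, c], n)
    K <- K / pmax(va, 1e-12)
  }
  K
}

#' Mean curvature from the signed distance transform
#'
#' Voxelizes the mesh, computes the signed Euclidean distance transform
#' (positive inside), takes the divergence of the unit gradient and
#' samples \code{H = -0.5 * div(n)} at the vertices by trilinear
#' interpolation. With the inside-positive sign convention convex
#' protrusions (blebs) score \code{H > 0}.
#'
#' @param mesh closed \linkS4class{SurfaceMesh}.
#' @param dilationRadius passed to \code{\link{voxelize}}.
#' @param sdfSigma Gaussian smoothing of the signed distance field
#'   before differentiation (suppresses the voxel-quantization staircase
#'   right at the interface; 0 disables).
#' @return per-vertex mean curvature in voxel^-1.
#' @export
meanCurvatureSDF <- function(mesh, dilationRadius = 1, sdfSigma = 1) {
  top <- surfaceTopology(mesh)
  if (top@boundaryLoops > 0L)
    stop("mesh is open; close it before curvature measurement")
  bv <- voxelize(mesh, dilationRadius = dilationRadius)
  phi <- signedDistance(bv)
  d0 <- dim(phi@data)
  phiS <- if (sdfSigma > 0)
    array(cpp_gauss3d(as.numeric(phi@data), d0[1], d0[2], d0[3],
                      sdfSigma), d0)
  else phi@data
  H <- divergenceMeanCurvature(phiS)
  pts <- sweep(mesh@vertices, 2, bv@origin)
  d <- dim(phi@data)
  cpp_trilinear(as.numeric(H), d[1], d[2], d[3], pts, 0)$values
}

# H = -1/2 div(grad phi / |grad phi|) on the grid, central differences.
divergenceMeanCurvature <- function(phi) {
  g <- arrayGradient(phi)
  mag <- sqrt(g$x^2 + g$y^2 + g$z^2)
  mag[mag < 1e-9] <- 1e-9
  nx <- g$x / mag; ny <- g$y / mag; nz <- g$z / mag
  -0.5 * (arrayGradient(nx)$x + arrayGradient(ny)$y + arrayGradient(nz)$z)
}

# Central-difference gradient of a 3D array (one-sided at borders).
arrayGradient <- function(a) {
  d <- dim(a)
  shift <- function(arr, by, axis) {
    idx <- lapply(d, seq_len)
    i <- pmin(pmax(seq_len(d[axis]) + by, 1L), d[axis])
    idx[[axis]] <- i
    do.call(`[`, c(list(arr), idx))
  }
  den <- function(axis) {
    w <- array(2, d)
    idx1 <- lapply(d, seq_len); idx1[[axis]] <- 1L
    idx2 <- lapply(d, seq_len); idx2[[axis]] <- d[axis]
    w <- do.call(`[<-`, c(list(w), idx1, list(1)))
    do.call(`[<-`, c(list(w), idx2, list(1)))
  }
  list(x = (shift(a, 1, 1) - shift(a, -1, 1)) / den(1),
       y = (shift(a, 1, 2) - shift(a, -1, 2)) / den(2),
       z = (shift(a, 1, 3) - shift(a, -1, 3)) / den(3))
}

# Isometric 2D flattening of every face: returns the 2D edge vectors
# (B-A, C-A) as a list of matrices.
flattenFaces <- function(V, F) {
  AB <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  AC <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  lab <- sqrt(rowSums(AB^2))
  dotp <- rowSums(AB * AC)
  cr <- cbind(AB[, 2] * AC[, 3] - AB[, 3] * AC[, 2],
              AB[, 3] * AC[, 1] - AB[, 1] * AC[, 3],
              AB[, 1] * AC[, 2] - AB[, 2] * AC[, 1])
  crn <- sqrt(rowSums(cr^2))
  list(b = cbind(lab, 0), c = cbind(dotp / lab, crn / lab))
}

# Aggregate criteria from per-element sigma ratios and lambdas.
distortionCriteria <- function(Q, lam, weights, theta = 0.5) {
  ok <- is.finite(Q) & is.finite(lam) & lam > 0
  w <- weights[ok] / sum(weights[ok])
  gQ <- sum(w * Q[ok])
  mips <- sum(w * (Q[ok] + 1 / Q[ok]))
  areaTerm <- lam[ok] + 1 / lam[ok]
  areaMips <- sum(w * (Q[ok] + 1 / Q[ok]) * areaTerm)
  meanAbsLnLam <- mean(abs(log(lam[ok])))
  c(equiareal_gap = abs(stats::median(lam[ok]) - 1),
    mips = mips,
    area_mips = areaMips,
    # mean absolute log area distortion: a symmetric magnitude that
    # decreases monotonically as the map approaches equiareal
    isometric = (1 - theta) * gQ + theta * meanAbsLnLam,
    mean_ln_lambda = mean(log(lam[ok])))
}

#' Per-face conformal and area distortion between corresponding meshes
#'
#' Both meshes must share the face list (bijective correspondence). Each
#' face pair is isometrically flattened to 2D; the singular values
#' sigma1 <= sigma2 of the affine map give the conformal error
#' \code{Q = sigma2/sigma1}, and the area-distortion factor is the ratio
#' of normalized area fractions \code{lambda = (a_src/sum)/(a_dst/sum)}.
#' Collapsed destination faces yield infinite Q; they are excluded from
#' the global aggregates but counted.
#'
#' @param src,dst \linkS4class{SurfaceMesh} objects with identical faces.
#' @param theta weight of the isometric criterion.
#' @return a \linkS4class{DistortionReport}.
#' @export
faceDistortion <- function(src, dst, theta = 0.5) {
  stopifnot(identical(dim(src@faces), dim(dst@faces)),
            nrow(src@vertices) == nrow(dst@vertices))
  f1 <- flattenFaces(src@vertices, src@faces)
  f2 <- flattenFaces(dst@vertices, dst@faces)
  # J = [b2 c2] %*% inv([b1 c1]) per face, 2x2
  det1 <- f1$b[, 1] * f1$c[, 2] - f1$b[, 2] * f1$c[, 1]
  i11 <- f1$c[, 2] / det1; i12 <- -f1$c[, 1] / det1
  i21 <- -f1$b[, 2] / det1; i22 <- f1$b[, 1] / det1
  j11 <- f2$b[, 1] * i11 + f2$c[, 1] * i21
  j12 <- f2$b[, 1] * i12 + f2$c[, 1] * i22
  j21 <- f2$b[, 2] * i11 + f2$c[, 2] * i21
  j22 <- f2$b[, 2] * i12 + f2$c[, 2] * i22
  tr <- j11^2 + j12^2 + j21^2 + j22^2
  dt <- (j11 * j22 - j12 * j21)^2
  disc <- sqrt(pmax(tr^2 / 4 - dt, 0))
  s2 <- sqrt(pmax(tr / 2 + disc, 0))
  s1 <- sqrt(pmax(tr / 2 - disc, 0))
  Q <- ifelse(s1 > 0, s2 / s1, Inf)
  a1 <- triangleAreas(src@vertices, src@faces)
  a2 <- triangleAreas(dst@vertices, dst@faces)
  lam <- (a1 / sum(a1)) / (a2 / sum(a2))
  ok <- is.finite(Q) & is.finite(lam) & lam > 0
  w <- a1
  crit <- distortionCriteria(Q, lam, w, theta)
  new("DistortionReport", Q = Q, lambda = lam,
      globalQ = sum((w[ok] / sum(w[ok])) * Q[ok]),
      globalLambda = mean(lam[ok]),
      medianLambda = stats::median(lam[ok]),
      criteria = crit, nInfinite = sum(!ok))
}

#' Per-pixel distortion of a UV lookup grid
#'
#' Jacobian columns are central differences of the pulled-back 3D
#' coordinates (periodic in u, one-sided at the polar rows);
#' \code{dA = |dS/du x dS/dv|}, Q is the singular-value ratio and lambda
#' compares the uniform pixel-area fraction with the dA fraction.
#'
#' @param uv a \linkS4class{UVGrid}.
#' @param theta weight of the isometric criterion.
#' @param periodicU treat columns as periodic in u (TRUE for full
#'   equirectangular grids; FALSE for planar patches).
#' @return a \linkS4class{DistortionReport} (per-pixel values flattened
#'   row-major).
#' @export
uvGridDistortion <- function(uv, theta = 0.5, periodicU = TRUE) {
  S <- uv@coords
  N <- dim(S)[1]; M <- dim(S)[2]
  if (N < 3L || M < 3L) stop("grid too small")
  # unique columns (drop duplicated seam for the periodic difference)
  Mu <- if (uv@seamDuplicated) M - 1L else M
  Su <- S[, seq_len(Mu), , drop = FALSE]
  if (periodicU) {
    right <- Su[, c(2:Mu, 1L), , drop = FALSE]
    left <- Su[, c(Mu, 1:(Mu - 1L)), , drop = FALSE]
    dSu <- (right - left) / 2
  } else {
    right <- Su[, c(2:Mu, Mu), , drop = FALSE]
    left <- Su[, c(1L, 1:(Mu - 1L)), , drop = FALSE]
    duA <- array(rep(ifelse(seq_len(Mu) %in% c(1L, Mu), 1, 2),
                     each = N), c(N, Mu, 3))
    dSu <- (right - left) / duA
  }
  up <- Su[c(1L, 1:(N - 1L)), , , drop = FALSE]
  dn <- Su[c(2:N, N), , , drop = FALSE]
  dv <- array(rep(ifelse(seq_len(N) %in% c(1L, N), 1, 2), Mu * 3), c(N, Mu, 3))
  dSv <- (dn - up) / dv
  crx <- dSu[, , 2] * dSv[, , 3] - dSu[, , 3] * dSv[, , 2]
  cry <- dSu[, , 3] * dSv[, , 1] - dSu[, , 1] * dSv[, , 3]
  crz <- dSu[, , 1] * dSv[, , 2] - dSu[, , 2] * dSv[, , 1]
  dA <- sqrt(crx^2 + cry^2 + crz^2)
  E <- dSu[, , 1]^2 + dSu[, , 2]^2 + dSu[, , 3]^2
  G <- dSv[, , 1]^2 + dSv[, , 2]^2 + dSv[, , 3]^2
  Fc <- dSu[, , 1] * dSv[, , 1] + dSu[, , 2] * dSv[, , 2] +
    dSu[, , 3] * dSv[, , 3]
  tr <- E + G
  dt <- E * G - Fc^2
  disc <- sqrt(pmax(tr^2 / 4 - dt, 0))
  s2 <- sqrt(pmax(tr / 2 + disc, 0))
  s1 <- sqrt(pmax(tr / 2 - disc, 0))
  Q <- ifelse(s1 > 0, s2 / s1, Inf)
  lam <- (1 / length(dA)) / (dA / sum(dA))
  ok <- is.finite(Q) & is.finite(lam) & lam > 0
  w <- as.numeric(dA)
  crit <- distortionCriteria(as.numeric(Q), as.numeric(lam), w, theta)
  new("DistortionReport", Q = as.numeric(Q), lambda = as.numeric(lam),
      globalQ = sum((w[ok] / sum(w[ok])) * as.numeric(Q)[ok]),
      globalLambda = mean(as.numeric(lam)[ok]),
      medianLambda = stats::median(as.numeric(lam)[ok]),
      criteria = crit, nInfinite = sum(!ok))
}

# Nearest-point distances from each row of P to the point cloud Vc,
# reusing the grid-accelerated triangle query with degenerate faces.
nearestPointDist <- function(Vc, P) {
  Fdeg <- cbind(seq_len(nrow(Vc)), seq_len(nrow(Vc)), seq_len(nrow(Vc)))
  storage.mode(Fdeg) <- "integer"
  cpp_closest_triangle(Vc, Fdeg, P)$dist
}

#' Compare two meshes: Chamfer, sliced Wasserstein-1, area and volume
#'
#' Chamfer distance is the mean of the two directional mean
#' nearest-vertex distances. SW1 is the max-sliced Wasserstein-1 between
#' the vertex sets: the maximum over random unit projections of the 1D
#' quantile distance, averaged over repeats. Area/volume differences are
#' percentages relative to \code{m2}; volumes are measured on binary
#' voxelizations.
#'
#' @param m1,m2 \linkS4class{SurfaceMesh} objects.
#' @param projections number of random projections per repeat.
#' @param repeats number of SW1 evaluations averaged.
#' @param seed RNG seed for the projections.
#' @param volumeFromVoxels measure volumes by voxelization (default) or
#'   by the divergence theorem.
#' @return a \linkS4class{MeshDifference}.
#' @export
compareMeshes <- function(m1, m2, projections = 50L, repeats = 10L,
                          seed = 1L, volumeFromVoxels = TRUE) {
  V1 <- m1@vertices; V2 <- m2@vertices
  d12 <- nearestPointDist(V2, V1)
  d21 <- nearestPointDist(V1, V2)
  cd <- 0.5 * (mean(d12) + mean(d21))
  set.seed(seed)
  n <- max(nrow(V1), nrow(V2))
  qs <- (seq_len(n) - 0.5) / n
  sw <- numeric(repeats)
  for (r in seq_len(repeats)) {
    best <- 0
    for (p in seq_len(projections)) {
      dir <- stats::rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      x1 <- sort(V1 %*% dir)
      x2 <- sort(V2 %*% dir)
      q1 <- stats::quantile(x1, qs, names = FALSE, type = 4)
      q2 <- stats::quantile(x2, qs, names = FALSE, type = 4)
      best <- max(best, mean(abs(q1 - q2)))
    }
    sw[r] <- best
  }
  A1 <- surfaceArea(m1); A2 <- surfaceArea(m2)
  if (volumeFromVoxels) {
    vol1 <- sum(voxelize(m1, dilationRadius = 1)@data)
    vol2 <- sum(voxelize(m2, dilationRadius = 1)@data)
  } else {
    vol1 <- abs(meshVolume(m1)); vol2 <- abs(meshVolume(m2))
  }
  new("MeshDifference", chamfer = cd, slicedW1 = mean(sw),
      deltaAreaPct = 100 * (A1 - A2) / A2,
      deltaVolumePct = 100 * (vol1 - vol2) / vol2,
      projections = as.integer(projections), repeats = as.integer(repeats),
      seed = as.integer(seed))
}
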