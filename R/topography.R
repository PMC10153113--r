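# Topographic (d,u,v) space: signed distance, normal propagation of the
# (u,v)-parameterized reference surface, volume resampling, topographic
# meshing and the inverse map back to Cartesian space.

#' Signed Euclidean distance transform of a binary volume
#'
#' Positive inside the foreground, negative outside.
#'
#' @param volume \linkS4class{BinaryVolume} with nonempty foreground and
#'   background.
#' @return a \linkS4class{SignedDistanceVolume}.
#' @export
signedDistance <- function(volume) {
  fg <- volume@data
  if (!any(fg)) stop("empty foreground")
  if (all(fg)) stop("all-foreground grid has no outside")
  d <- dim(fg)
  dIn <- cpp_edt3d(!fg, d[1], d[2], d[3])   # distance to background
  dOut <- cpp_edt3d(fg, d[1], d[2], d[3])   # distance to foreground
  phi <- array(dIn - dOut, d)
  new("SignedDistanceVolume", data = phi, origin = volume@origin)
}

# 2D box smoothing of a shell-coordinate image: periodic in u (columns,
# seam-aware), clamped in v (rows).
boxSmoothShell <- function(img, window = 5L) {
  if (window <= 1L) return(img)
  half <- window %/% 2L
  nr <- nrow(img); nc <- ncol(img)
  core <- img[, -nc, drop = FALSE]  # drop duplicated seam
  m <- ncol(core)
  ext <- cbind(core[, (m - half + 1L):m, drop = FALSE], core,
               core[, 1:half, drop = FALSE])
  ext <- rbind(ext[rep(1L, half), , drop = FALSE], ext,
               ext[rep(nr, half), , drop = FALSE])
  # separable running mean
  cs <- apply(ext, 2, cumsum)
  rows <- (cs[(window):(nr + 2L * half), , drop = FALSE] -
             rbind(0, cs[1:(nr + half * 2L - window), , drop = FALSE])) /
    window
  cs2 <- t(apply(rows, 1, cumsum))
  out <- (cs2[, (window):(m + 2L * half), drop = FALSE] -
            cbind(0, cs2[, 1:(m + half * 2L - window), drop = FALSE])) /
    window
  cbind(out, out[, 1])
}

#' Grow a topographic (d,u,v) coordinate space
#'
#' The d = 0 shell is the (u,v)-parameterized reference surface (the UV
#' grid's coordinates). Outward shells are grown by explicit Euler steps
#' of \code{alpha} voxels along the outward unit gradient of the signed
#' distance function, with per-step 2D box smoothing (window 5) of the
#' shell coordinate images to maintain bijectivity; inward shells use the
#' inward gradient. \code{dOut = "auto"} expands until the whole shell is
#' at least 2 voxels outside the foreground that the signed distance was
#' built from.
#'
#' @param uv \linkS4class{UVGrid} of the reference surface (coordinates
#'   in the mesh frame).
#' @param sdf \linkS4class{SignedDistanceVolume}.
#' @param alpha step size in voxels.
#' @param dIn inward step count.
#' @param dOut outward step count or \code{"auto"}.
#' @param smoothWindow box window (pixels) for per-step shell smoothing.
#' @param maxDOut cap for the automatic expansion.
#' @param enclose for \code{dOut = "auto"}: the \linkS4class{BinaryVolume}
#'   (e.g. the input cell) that the outward shells must fully enclose;
#'   defaults to the foreground of \code{sdf}.
#' @return a \linkS4class{TopographicSpace}.
#' @export
buildTopographicSpace <- function(uv, sdf, alpha = 0.5, dIn = 10L,
                                  dOut = "auto", smoothWindow = 5L,
                                  maxDOut = 400L, enclose = NULL) {
  S0 <- uv@coords
  N <- dim(S0)[1]; M <- dim(S0)[2]
  d <- dim(sdf@data)
  # smooth the distance field before differentiating: the discrete EDT
  # carries a voxel staircase whose gradient noise bends the shells
  phiSm <- array(cpp_gauss3d(as.numeric(sdf@data), d[1], d[2], d[3], 1),
                 d)
  g <- arrayGradient(phiSm)
  mag <- sqrt(g$x^2 + g$y^2 + g$z^2)
  mag[mag < 1e-9] <- 1e-9
  gx <- as.numeric(g$x / mag); gy <- as.numeric(g$y / mag)
  gz <- as.numeric(g$z / mag)
  phiV <- as.numeric(sdf@data)
  sampleGrid <- function(P) {
    # P in mesh frame -> grid frame
    Pg <- sweep(P, 2, sdf@origin)
    list(gx = cpp_trilinear(gx, d[1], d[2], d[3], Pg, 0),
         gy = cpp_trilinear(gy, d[1], d[2], d[3], Pg, 0),
         gz = cpp_trilinear(gz, d[1], d[2], d[3], Pg, 0),
         phi = cpp_trilinear(phiV, d[1], d[2], d[3], Pg, -Inf))
  }
  stepShell <- function(P, direction) {
    if (alpha == 0) return(P)  # degenerate: every shell is the d=0 shell
    s <- sampleGrid(P)
    if (s$gx$n_outside > 0)
      stop("topographic shell left the signed-distance grid; pad the volume")
    # phi is positive inside: outward = -grad(phi)
    disp <- direction * alpha *
      cbind(s$gx$values, s$gy$values, s$gz$values)
    P2 <- P - disp
    for (c in 1:3) {
      img <- matrix(P2[, c], N, M)
      P2[, c] <- as.numeric(boxSmoothShell(img, smoothWindow))
    }
    P2
  }
  P0 <- matrix(S0, N * M, 3)
  auto <- identical(dOut, "auto")
  encDist <- NULL; encOrigin <- NULL; encDim <- NULL
  if (auto) {
    if (is.null(enclose)) {
      encDist <- -phiV  # distance convention: negative inside
      encOrigin <- sdf@origin; encDim <- d
    } else {
      eb <- enclose@data
      encDim <- dim(eb)
      # signed distance of the volume to enclose (negative inside)
      encDist <- cpp_edt3d(eb, encDim[1], encDim[2], encDim[3]) -
        cpp_edt3d(!eb, encDim[1], encDim[2], encDim[3])
      encOrigin <- enclose@origin
    }
  }
  outShells <- list()
  P <- P0
  nOut <- if (auto) maxDOut else as.integer(dOut)
  for (k in seq_len(nOut)) {
    P <- stepShell(P, +1)
    outShells[[k]] <- P
    if (auto) {
      Pg <- sweep(P, 2, encOrigin)
      dd <- cpp_trilinear(encDist, encDim[1], encDim[2], encDim[3], Pg,
                          1e6)$values
      if (min(dd) > 2) { nOut <- k; break }
    }
  }
  inShells <- list()
  P <- P0
  for (k in seq_len(dIn)) {
    P <- stepShell(P, -1)
    inShells[[k]] <- P
  }
  D <- length(inShells) + 1L + length(outShells)
  coords <- array(NA_real_, c(D, N, M, 3))
  for (k in seq_along(inShells))
    coords[dIn + 1L - k, , , ] <- array(inShells[[k]], c(N, M, 3))
  coords[dIn + 1L, , , ] <- S0
  for (k in seq_along(outShells))
    coords[dIn + 1L + k, , , ] <- array(outShells[[k]], c(N, M, 3))
  new("TopographicSpace", coords = coords, alpha = alpha,
      dIn = as.integer(dIn), dOut = as.integer(length(outShells)),
      uv = uv)
}

#' Resample a Cartesian volume into topographic space
#'
#' Trilinear sampling of the volume at the (x,y,z) lookup coordinates of
#' every (d,u,v) voxel.
#'
#' @param space \linkS4class{TopographicSpace}.
#' @param intensity 3D numeric array, or a \linkS4class{BinaryVolume}.
#' @param origin frame offset of \code{intensity} (taken from a
#'   BinaryVolume automatically).
#' @param fill value for out-of-grid samples.
#' @return 3D array of dim (D, N, M) in (d, v, u) order; attribute
#'   \code{"n_outside"} counts clamped samples.
#' @export
resampleVolume <- function(space, intensity, origin = c(0, 0, 0),
                           fill = 0) {
  if (is(intensity, "BinaryVolume")) {
    origin <- intensity@origin
    intensity <- array(as.numeric(intensity@data), dim(intensity@data))
  }
  d <- dim(intensity)
  dims <- dim(space@coords)
  P <- matrix(space@coords, prod(dims[1:3]), 3)
  P <- sweep(P, 2, origin)
  s <- cpp_trilinear(as.numeric(intensity), d[1], d[2], d[3], P, fill)
  out <- array(s$values, dims[1:3])
  attr(out, "n_outside") <- s$n_outside
  out
}

#' Mesh the topographic binary volume
#'
#' Gaussian smoothing (sigma 1), isosurfacing at 0.5, largest component,
#' uniform remeshing (default half the isosurface vertex count). Vertex
#' coordinates are (d, v, u) voxel indices of the topographic volume.
#'
#' @param topoBinary 3D logical/numeric array in (d, v, u) order.
#' @param remeshFraction target vertex fraction.
#' @param closeBottom keep the flat closing plate where the solid cell
#'   interior reaches the bottom of the depth domain (TRUE, watertight;
#'   right choice for Cartesian reconstruction) or strip it, leaving an
#'   open terrain sheet (right choice for height-based segmentation).
#' @return \linkS4class{SurfaceMesh} with tag \code{"topographic"}.
#' @export
topographicMesh <- function(topoBinary, remeshFraction = 0.5,
                            closeBottom = TRUE, maxVertices = 20000L,
                            relaxIterations = 3L) {
  if (!any(topoBinary > 0.5)) stop("empty topographic binary")
  # zero-pad so the terrain closes into a watertight surface even where
  # the solid cell interior reaches the bottom of the depth domain
  d0 <- dim(topoBinary)
  padded <- array(FALSE, d0 + 2L)
  padded[2:(d0[1] + 1L), 2:(d0[2] + 1L), 2:(d0[3] + 1L)] <-
    topoBinary > 0.5
  vol <- BinaryVolume(padded, origin = c(-1, -1, -1))
  m <- meshFromVolume(vol, isovalue = 0.5, remeshFraction = NULL,
                      gaussianSigma = 1)
  if (!is.null(remeshFraction)) {
    target <- min(maxVertices,
                  max(16L, round(remeshFraction * nrow(m@vertices))))
    m <- remeshUniform(m, target, relaxIterations = relaxIterations)
  }
  if (!closeBottom) {
    dcoord <- m@vertices[, 1]
    plate <- dcoord < 1.0
    keep <- !(plate[m@faces[, 1]] & plate[m@faces[, 2]] &
                plate[m@faces[, 3]])
    m <- submeshByFaces(m, which(keep))$mesh
    m <- largestComponent(m)
  }
  m@representation <- "topographic"
  m
}

#' Map topographic coordinates (or a topographic mesh) back to Cartesian
#'
#' Trilinear interpolation into the (d,u,v) -> (x,y,z) lookup volume.
#' Out-of-domain coordinates are clamped (with a warning count) or, in
#' strict mode, raise an error.
#'
#' @param space \linkS4class{TopographicSpace}.
#' @param x nx3 matrix of (d, v, u) coordinates (1-based voxel indices of
#'   the topographic volume), or a topographic \linkS4class{SurfaceMesh}.
#' @param strict error on out-of-domain coordinates.
#' @return coordinates matrix, or a \linkS4class{SurfaceMesh} with tag
#'   \code{"cartesian"} and unchanged faces.
#' @export
topoToCartesian <- function(space, x, strict = FALSE) {
  mesh <- NULL
  if (is(x, "SurfaceMesh")) { mesh <- x; x <- x@vertices }
  dims <- dim(space@coords)
  lo <- c(1, 1, 1); hi <- dims[1:3]
  outside <- x[, 1] < lo[1] | x[, 2] < lo[2] | x[, 3] < lo[3] |
    x[, 1] > hi[1] | x[, 2] > hi[2] | x[, 3] > hi[3]
  if (any(outside)) {
    if (strict) stop(sum(outside), " coordinates out of the (d,u,v) domain")
    warning(sum(outside), " out-of-domain coordinates clamped")
    for (c in 1:3) x[, c] <- pmin(pmax(x[, c], lo[c]), hi[c])
  }
  out <- matrix(0, nrow(x), 3)
  for (c in 1:3) {
    ch <- as.numeric(space@coords[, , , c])
    out[, c] <- cpp_trilinear(ch, dims[1], dims[2], dims[3], x, 0)$values
  }
  if (is.null(mesh)) return(out)
  res <- mesh
  res@vertices <- out
  res@representation <- "cartesian"
  res
}

# Differential volume element of every (d,u,v) voxel (triple product of
# the central-difference Jacobian columns).
topographicDV <- function(space) {
  A <- space@coords
  dims <- dim(A)
  ax <- function(axis, by) {
    idx <- lapply(dims[1:3], seq_len)
    idx[[axis]] <- pmin(pmax(idx[[axis]] + by, 1L), dims[axis])
    A[idx[[1]], idx[[2]], idx[[3]], , drop = FALSE]
  }
  den <- function(axis) {
    v <- rep(2, dims[axis])
    v[c(1, dims[axis])] <- 1
    v
  }
  dd <- (ax(1, 1) - ax(1, -1)) / array(den(1), dims)
  dv <- (ax(2, 1) - ax(2, -1)) /
    array(rep(den(2), each = dims[1]), dims)
  du <- (ax(3, 1) - ax(3, -1)) /
    array(rep(den(3), each = dims[1] * dims[2]), dims)
  cr1 <- du[, , , 2] * dv[, , , 3] - du[, , , 3] * dv[, , , 2]
  cr2 <- du[, , , 3] * dv[, , , 1] - du[, , , 1] * dv[, , , 3]
  cr3 <- du[, , , 1] * dv[, , , 2] - du[, , , 2] * dv[, , , 1]
  abs(cr1 * dd[, , , 1] + cr2 * dd[, , , 2] + cr3 * dd[, , , 3])
}
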