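# Equirectangular UV mapping: unwrapping-axis selection by weighted PCA,
# lookup-grid construction by barycentric pullback, scalar pullback,
# spherical padding and distortion-corrected averaging.

#' Optimal unwrapping axis by weighted PCA
#'
#' Eigendecomposition of the 3x3 weighted covariance of the spherical
#' vertex positions. The smallest eigenvector is the optimal north-south
#' unwrapping axis. Signs of e1, e2 are fixed to positive x/y components
#' and e3 = e1 x e2, giving a proper rotation. Degenerate spectra
#' (eigenvalue ties within 1e-6 relative) fall back to the identity.
#'
#' @param sphere \linkS4class{SurfaceMesh} on the unit sphere (or vertex
#'   matrix).
#' @param weights nonnegative per-vertex weights, not all zero.
#' @return list: \code{rotation} (the applied rotation, i.e. t(Rprime)),
#'   \code{Rprime}, \code{eigenvalues}, \code{degenerate}.
#' @export
optimalRotationPCA <- function(sphere, weights) {
  V <- if (is(sphere, "SurfaceMesh")) sphere@vertices else sphere
  if (any(weights < 0) || all(weights == 0))
    stop("weights must be nonnegative and not all zero")
  w <- weights / sum(weights)
  A <- crossprod(V * sqrt(w))
  eg <- eigen(A, symmetric = TRUE)
  ev <- eg$values
  degenerate <- any(abs(diff(ev)) < 1e-6 * max(abs(ev)))
  if (degenerate) {
    Rp <- diag(3)
  } else {
    e1 <- eg$vectors[, 1] * sign(eg$vectors[1, 1] + (eg$vectors[1, 1] == 0))
    e2 <- eg$vectors[, 2] * sign(eg$vectors[2, 2] + (eg$vectors[2, 2] == 0))
    e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
            e1[3] * e2[1] - e1[1] * e2[3],
            e1[1] * e2[2] - e1[2] * e2[1])
    Rp <- cbind(e1, e2, e3)
  }
  list(rotation = t(Rp), Rprime = Rp, eigenvalues = ev,
       degenerate = degenerate)
}

# Differential areas of a UV coordinate grid (shared by UVGrid
# construction and uvGridDistortion). periodicU = FALSE treats the
# columns as a plain (non-wrapping) patch.
computeUVdA <- function(S, seamDuplicated = TRUE, periodicU = TRUE) {
  N <- dim(S)[1]; M <- dim(S)[2]
  Mu <- if (seamDuplicated) M - 1L else M
  Su <- S[, seq_len(Mu), , drop = FALSE]
  if (periodicU) {
    right <- Su[, c(2:Mu, 1L), , drop = FALSE]
    left <- Su[, c(Mu, 1:(Mu - 1L)), , drop = FALSE]
    dSu <- (right - left) / 2
  } else {
    right <- Su[, c(2:Mu, Mu), , drop = FALSE]
    left <- Su[, c(1L, 1:(Mu - 1L)), , drop = FALSE]
    du <- array(rep(ifelse(seq_len(Mu) %in% c(1L, Mu), 1, 2),
                    each = N), c(N, Mu, 3))
    dSu <- (right - left) / du
  }
  up <- Su[c(1L, 1:(N - 1L)), , , drop = FALSE]
  dn <- Su[c(2:N, N), , , drop = FALSE]
  dv <- array(rep(ifelse(seq_len(N) %in% c(1L, N), 1, 2), Mu * 3),
              c(N, Mu, 3))
  dSv <- (dn - up) / dv
  crx <- dSu[, , 2] * dSv[, , 3] - dSu[, , 3] * dSv[, , 2]
  cry <- dSu[, , 3] * dSv[, , 1] - dSu[, , 1] * dSv[, , 3]
  crz <- dSu[, , 1] * dSv[, , 2] - dSu[, , 2] * dSv[, , 1]
  dA <- sqrt(crx^2 + cry^2 + crz^2)
  if (seamDuplicated) dA <- cbind(dA, dA[, 1])
  dA
}

#' Build an equirectangular UV lookup grid
#'
#' Rows sample the polar angle v in [0, pi] (north at row 1), columns the
#' azimuth u in [-pi, pi] with the seam column duplicated, i.e. an
#' N x (2N+1) grid. Each pixel direction is matched to its nearest
#' spherical triangle, the barycentric weights are recorded, and the 3D
#' coordinates of the target mesh (reference, input, or any mesh sharing
#' the sphere's faces) are pulled back as the convex combination of the
#' matched corner vertices.
#'
#' @param sp \linkS4class{SphereParam} (or a sphere
#'   \linkS4class{SurfaceMesh}).
#' @param target mesh bijective to the sphere (same face list); defaults
#'   to the reference mesh of \code{sp}.
#' @param N number of rows (>= 8); columns are 2N(+1).
#' @param rotation 3x3 applied rotation from
#'   \code{\link{optimalRotationPCA}} (identity if NULL).
#' @param duplicateSeam keep the duplicated seam column (default TRUE).
#' @return a \linkS4class{UVGrid}.
#' @export
buildUVGrid <- function(sp, target = NULL, N = 256L, rotation = NULL,
                        duplicateSeam = TRUE) {
  if (is(sp, "SphereParam")) {
    sphere <- sp@sphere
    if (is.null(target)) target <- sp@reference
  } else {
    sphere <- sp
    if (is.null(target)) target <- sphere
  }
  if (N < 8L) stop("N must be at least 8")
  stopifnot(identical(dim(sphere@faces), dim(target@faces)))
  if (max(abs(sqrt(rowSums(sphere@vertices^2)) - 1)) > 1e-3)
    stop("the grid must be built from a unit-sphere mesh; pass the ",
         "target surface via `target`")
  if (is.null(rotation)) rotation <- diag(3)
  M <- 2L * N + 1L
  vAng <- seq(0, pi, length.out = N)
  uAng <- seq(-pi, pi, length.out = M)
  P <- cbind(rep(sin(vAng), M) * rep(cos(uAng), each = N),
             rep(sin(vAng), M) * rep(sin(uAng), each = N),
             rep(cos(vAng), M))
  # rotate the sphere into the unwrapping frame: v' = R v, i.e. V %*% t(R)
  Vrot <- sphere@vertices %*% t(rotation)
  q <- cpp_closest_triangle(Vrot, sphere@faces, P)
  tri <- sphere@faces[q$face, , drop = FALSE]
  Vt <- target@vertices
  coords <- q$bary[, 1] * Vt[tri[, 1], , drop = FALSE] +
    q$bary[, 2] * Vt[tri[, 2], , drop = FALSE] +
    q$bary[, 3] * Vt[tri[, 3], , drop = FALSE]
  S <- array(coords, c(N, M, 3))
  # exact seam duplication
  S[, M, ] <- S[, 1, ]
  fIdx <- matrix(q$face, N, M); fIdx[, M] <- fIdx[, 1]
  W <- array(q$bary, c(N, M, 3)); W[, M, ] <- W[, 1, ]
  dA <- computeUVdA(S, TRUE)
  grid <- new("UVGrid", coords = S, faceIndex = fIdx, weights = W,
              dA = dA, rotation = rotation, faces = sphere@faces,
              seamDuplicated = TRUE)
  if (!duplicateSeam) {
    grid@coords <- S[, -M, , drop = FALSE]
    grid@faceIndex <- fIdx[, -M, drop = FALSE]
    grid@weights <- W[, -M, , drop = FALSE]
    grid@dA <- dA[, -M, drop = FALSE]
    grid@seamDuplicated <- FALSE
  }
  grid
}

#' Pull a per-vertex scalar field back onto the UV grid
#'
#' @param uv \linkS4class{UVGrid}.
#' @param field numeric vector on the vertices of the mesh the grid was
#'   built from.
#' @return numeric matrix (image) of the pulled-back field.
#' @export
pullbackScalar <- function(uv, field) {
  if (length(field) != max(uv@faces))
    stop("field length does not match the linked mesh")
  tri <- uv@faces[uv@faceIndex, , drop = FALSE]
  img <- uv@weights[, , 1] * field[tri[, 1]] +
    uv@weights[, , 2] * field[tri[, 2]] +
    uv@weights[, , 3] * field[tri[, 3]]
  matrix(img, nrow(uv@faceIndex), ncol(uv@faceIndex))
}

#' Spherically-consistent padding of an equirectangular image
#'
#' Left/right edges wrap periodically. Rows beyond the poles reflect
#' about the polar row combined with the pole-crossing azimuthal shift of
#' half a period (a point just past the north pole at azimuth u is the
#' point just below it at azimuth u + pi).
#'
#' @param image 2D matrix (rows = polar angle).
#' @param pad pad width (< min(dim)).
#' @return padded matrix of dim (nr + 2*pad, nc + 2*pad).
#' @export
padSpherical <- function(image, pad) {
  nr <- nrow(image); nc <- ncol(image)
  stopifnot(pad < min(nr, nc))
  if (pad == 0L) return(image)
  wrapped <- cbind(image[, (nc - pad + 1L):nc, drop = FALSE], image,
                   image[, 1:pad, drop = FALSE])
  half <- (nc %/% 2L)
  shift <- function(rows) {
    block <- image[rows, c((half + 1L):nc, 1:half), drop = FALSE]
    cbind(block[, (nc - pad + 1L):nc, drop = FALSE], block,
          block[, 1:pad, drop = FALSE])
  }
  top <- shift(seq(pad + 1L, 2L, by = -1L))
  bottom <- shift(seq(nr - 1L, nr - pad, by = -1L))
  rbind(top, wrapped, bottom)
}

#' Differential-area-weighted mean over a UV mask
#'
#' \code{sum(F * dA * mask) / sum(dA * mask)}: the distortion-corrected
#' average of an unwrapped signal over a (u,v) region.
#'
#' @param image signal matrix.
#' @param dA differential-area matrix.
#' @param mask logical matrix.
#' @return scalar weighted mean.
#' @export
weightedUVMean <- function(image, dA, mask) {
  stopifnot(identical(dim(image), dim(dA)), identical(dim(image), dim(mask)))
  if (!any(mask)) stop("empty mask")
  sum(image[mask] * dA[mask]) / sum(dA[mask])
}
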