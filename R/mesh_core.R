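# Voxelization, isosurface meshing, remeshing, topology and scalar
# transfer between meshes.

#' Topology report of a triangle mesh
#'
#' Counts vertices, undirected edges and faces, computes the Euler
#' characteristic chi = V - E + F, the number of boundary loops b (edges
#' with a single incident face), and for manifold meshes the genus from
#' chi = 2 - 2g - b.
#'
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @return a \linkS4class{TopologyReport}.
#' @export
surfaceTopology <- function(mesh) {
  F <- mesh@faces
  em <- meshEdges(F)
  nV <- nrow(mesh@vertices)
  nE <- nrow(em$edges)
  nF <- nrow(F)
  cnt <- table(em$key)
  manifold <- all(cnt <= 2L)
  nBndEdges <- sum(cnt == 1L)
  loops <- if (nBndEdges > 0L) length(boundaryLoops(F)) else 0L
  chi <- nV - nE + nF
  genus <- if (manifold) as.integer(round((2 - chi - loops) / 2)) else NA_integer_
  new("TopologyReport", nVertices = as.integer(nV), nEdges = as.integer(nE),
      nFaces = as.integer(nF), euler = as.integer(chi), genus = genus,
      boundaryLoops = as.integer(loops),
      watertight = manifold && loops == 0L, manifold = manifold)
}

#' Voxelize a closed surface mesh into a binary volume
#'
#' The mesh is midpoint-subdivided until its mean edge length is below one
#' voxel, the face barycenters are rasterized into a padded grid, and the
#' raster is morphologically closed (dilation by a ball of
#' \code{dilationRadius}, binary filling of the enclosed region, erosion)
#' so that small holes in the input do not leak. The erosion radius is
#' \code{dilationRadius + 0.5}: the extra half voxel compensates the
#' rasterization thickness so enclosed volumes are unbiased.
#'
#' @param mesh closed \linkS4class{SurfaceMesh} (small holes tolerated).
#' @param dilationRadius ball radius in voxels (>= 0).
#' @param gaussianSigma optional Gaussian smoothing of the final binary
#'   (re-thresholded at 0.5); 0 disables.
#' @param pad grid padding; defaults to \code{max(dilationRadius + 2, 4)}.
#' @return a \linkS4class{BinaryVolume} whose \code{origin} maps mesh
#'   coordinates into the grid.
#' @export
voxelize <- function(mesh, dilationRadius = 1, gaussianSigma = 0,
                     pad = NULL) {
  if (nrow(mesh@faces) == 0L) stop("cannot voxelize an empty mesh")
  stopifnot(dilationRadius >= 0)
  if (is.null(pad)) pad <- max(dilationRadius + 2, 4)
  V <- mesh@vertices
  lo <- floor(apply(V, 2, min)) - pad
  hi <- ceiling(apply(V, 2, max)) + pad
  dims <- as.integer(hi - lo + 1)
  # origin: mesh point p lives at array coordinate p - origin (1-based)
  origin <- lo - 1
  m <- mesh
  while (meanEdgeLength(m) >= 1) m <- subdivideMidpoint(m)
  Vm <- m@vertices; Fm <- m@faces
  bary <- (Vm[Fm[, 1], , drop = FALSE] + Vm[Fm[, 2], , drop = FALSE] +
           Vm[Fm[, 3], , drop = FALSE]) / 3
  pts <- rbind(bary, Vm)
  ijk <- round(sweep(pts, 2, origin))
  ok <- ijk[, 1] >= 1 & ijk[, 2] >= 1 & ijk[, 3] >= 1 &
    ijk[, 1] <= dims[1] & ijk[, 2] <= dims[2] & ijk[, 3] <= dims[3]
  if (!all(ok)) stop("mesh does not fit the padded grid")
  fg <- array(FALSE, dims)
  fg[ijk] <- TRUE
  if (dilationRadius > 0) {
    d <- array(cpp_edt3d(fg, dims[1], dims[2], dims[3]), dims)
    fg <- d <= dilationRadius
  }
  outside <- array(cpp_outside_mask(fg, dims[1], dims[2], dims[3]), dims)
  filled <- !outside
  dbg <- array(cpp_edt3d(!filled, dims[1], dims[2], dims[3]), dims)
  fg <- dbg > dilationRadius + 0.5
  if (gaussianSigma > 0) {
    sm <- array(cpp_gauss3d(as.numeric(fg), dims[1], dims[2], dims[3],
                            gaussianSigma), dims)
    fg <- sm > 0.5
  }
  if (!any(fg)) stop("voxelization produced an empty foreground")
  BinaryVolume(fg, origin = origin)
}

#' Extract a surface mesh from a binary volume
#'
#' The binary is Gaussian-smoothed (default sigma 1), isosurfaced at the
#' given isovalue by marching tetrahedra (watertight by construction),
#' restricted to its largest connected component and remeshed by uniform
#' vertex clustering with tangential relaxation to
#' \code{remeshFraction * (isosurface vertex count)} vertices. Vertex
#' coordinates are returned in the mesh frame of the volume (its origin is
#' added back).
#'
#' @param volume \linkS4class{BinaryVolume}.
#' @param isovalue isosurface level (default 0.5).
#' @param remeshFraction target vertex fraction; \code{NULL} skips
#'   remeshing.
#' @param gaussianSigma smoothing applied before isosurfacing.
#' @return a \linkS4class{SurfaceMesh} (tag \code{"cartesian"}).
#' @export
meshFromVolume <- function(volume, isovalue = 0.5, remeshFraction = 0.9,
                           gaussianSigma = 1) {
  vol <- volume@data
  if (!any(vol)) stop("volume has empty foreground")
  dims <- dim(vol)
  f <- as.numeric(vol)
  if (gaussianSigma > 0)
    f <- cpp_gauss3d(f, dims[1], dims[2], dims[3], gaussianSigma)
  mt <- cpp_marching_tets(f, dims[1], dims[2], dims[3], isovalue)
  if (nrow(mt$V) == 0L) stop("isosurface is empty at this isovalue")
  V <- mt$V + 1  # 0-based grid coords -> 1-based array coords
  F <- mt$F + 1L
  V <- sweep(V, 2, volume@origin, `+`)
  # keep sliver faces: the marching-tets surface is watertight as emitted
  # and consistently oriented by the inside/outside rule
  mesh <- SurfaceMesh(V, F, dropDegenerate = FALSE)
  mesh <- largestComponent(mesh)
  if (meshVolume(mesh) < 0) mesh@faces <- mesh@faces[, c(1, 3, 2)]
  if (!is.null(remeshFraction)) {
    target <- max(16L, round(remeshFraction * nrow(mesh@vertices)))
    mesh <- remeshUniform(mesh, target)
  }
  mesh
}

#' Uniform isotropic remeshing
#'
#' Decimates to the target vertex count by shortest-edge collapse with the
#' link condition (topology preserving), then improves face quality by
#' Lloyd-style tangential relaxation: each vertex repeatedly moves to the
#' centroid of its neighbors and is reprojected onto the input surface.
#' Collapsing the shortest edge first equalizes edge lengths, so the
#' result is a uniform, near-equilateral remesh.
#'
#' @param mesh input \linkS4class{SurfaceMesh}.
#' @param targetVertices desired vertex count (approximate, within ~10%).
#' @param relaxIterations tangential relaxation sweeps.
#' @return remeshed \linkS4class{SurfaceMesh}.
#' @export
remeshUniform <- function(mesh, targetVertices, relaxIterations = 10L) {
  V <- mesh@vertices; F <- mesh@faces
  dec <- cpp_decimate(V, F, as.integer(targetVertices))
  out <- SurfaceMesh(dec$V, dec$F, representation = mesh@representation,
                     dropDegenerate = FALSE)
  out <- largestComponent(out)
  out@faces <- orientFaces(out@vertices, out@faces)
  # tangential Lloyd relaxation with reprojection
  if (relaxIterations > 0L) {
    E <- meshEdges(out@faces)$edges
    n <- nrow(out@vertices)
    deg <- tapplySum(rep(1, 2 * nrow(E)), c(E[, 1], E[, 2]), n)
    for (it in seq_len(relaxIterations)) {
      W <- out@vertices
      acc <- matrix(0, n, 3)
      for (d in 1:3) {
        acc[, d] <- tapplySum(c(W[E[, 2], d], W[E[, 1], d]),
                              c(E[, 1], E[, 2]), n)
      }
      cent <- acc / pmax(deg, 1)
      proj <- cpp_closest_triangle(V, F, cent)
      out@vertices <- proj$point
    }
  }
  out
}

# Close small holes left by cluster collapse: repeatedly drop duplicated
# face triples and fan-fill boundary loops (triangle for 3-loops, centroid
# fan otherwise).
healMesh <- function(V, F) {
  for (round in 1:4) {
    keep <- F[, 1] != F[, 2] & F[, 2] != F[, 3] & F[, 1] != F[, 3]
    F <- F[keep, , drop = FALSE]
    key <- apply(cbind(pmin(F[, 1], pmin(F[, 2], F[, 3])),
                       F[, 1] + F[, 2] + F[, 3] -
                         pmin(F[, 1], pmin(F[, 2], F[, 3])) -
                         pmax(F[, 1], pmax(F[, 2], F[, 3])),
                       pmax(F[, 1], pmax(F[, 2], F[, 3]))), 1, paste,
                 collapse = " ")
    dup <- key %in% key[duplicated(key)]
    F <- F[!dup, , drop = FALSE]
    loops <- boundaryLoops(F)
    if (length(loops) == 0L) break
    for (lp in loops) {
      if (length(lp) < 3L) next
      if (length(lp) == 3L) {
        F <- rbind(F, rev(lp))
      } else {
        cen <- colMeans(V[lp, , drop = FALSE])
        V <- rbind(V, cen)
        ci <- nrow(V)
        nlp <- length(lp)
        F <- rbind(F, cbind(lp[c(2:nlp, 1)], lp, ci))
      }
    }
    storage.mode(F) <- "integer"
  }
  list(V = V, F = F)
}

#' Transfer a per-vertex scalar field between meshes
#'
#' Each destination vertex is matched to its nearest source triangle
#' (grid-accelerated exact query); \code{"barycentric"} returns the convex
#' barycentric combination of the source corner values, \code{"nearest"}
#' copies the value of the nearest corner.
#'
#' @param src,dst \linkS4class{SurfaceMesh} objects occupying overlapping
#'   space.
#' @param field numeric vector on \code{src} vertices.
#' @param method \code{"barycentric"} or \code{"nearest"}.
#' @return numeric vector on \code{dst} vertices.
#' @export
transferScalars <- function(src, dst, field,
                            method = c("barycentric", "nearest")) {
  method <- match.arg(method)
  if (length(field) == 0L) stop("empty field")
  stopifnot(length(field) == nrow(src@vertices))
  q <- cpp_closest_triangle(src@vertices, src@faces, dst@vertices)
  tri <- src@faces[q$face, , drop = FALSE]
  if (method == "barycentric") {
    q$bary[, 1] * field[tri[, 1]] + q$bary[, 2] * field[tri[, 2]] +
      q$bary[, 3] * field[tri[, 3]]
  } else {
    pick <- max.col(q$bary, ties.method = "first")
    field[tri[cbind(seq_len(nrow(tri)), pick)]]
  }
}
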