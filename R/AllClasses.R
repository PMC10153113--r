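#' @import methods
#' @importFrom Matrix sparseMatrix Diagonal rowSums colSums t solve crossprod
#' @importFrom Rcpp evalCpp
#' @importFrom stats median sd quantile rnorm runif kmeans setNames lm IQR
#' @importFrom utils head tail
#' @useDynLib topomesh, .registration = TRUE
NULL

REPRESENTATION_TAGS <- c("cartesian", "reference", "sphere", "topographic",
                         "plane")

#' Triangle surface mesh with a representation tag
#'
#' The central container of the package: a triangle mesh given by an
#' \code{n x 3} vertex coordinate matrix (voxel units, axis order matching
#' the source volume) and an \code{m x 3} face index matrix (1-based),
#' together with a representation tag recording which of the five spaces
#' the coordinates live in and an optional list of named per-vertex scalar
#' fields.
#'
#' @slot vertices numeric matrix, one 3D point per row.
#' @slot faces integer matrix, one vertex index triple per row.
#' @slot representation one of \code{"cartesian"}, \code{"reference"},
#'   \code{"sphere"}, \code{"topographic"}, \code{"plane"}.
#' @slot scalars named list of numeric vectors, each of length
#'   \code{nrow(vertices)}.
#' @export
setClass("SurfaceMesh",
  representation(vertices = "matrix", faces = "matrix",
                 representation = "character", scalars = "list"),
  prototype(representation = "cartesian", scalars = list()))

setValidity("SurfaceMesh", function(object) {
  v <- object@vertices; f <- object@faces
  if (ncol(v) != 3L) return("vertices must have 3 columns")
  if (nrow(f) > 0L) {
    if (ncol(f) != 3L) return("faces must have 3 columns")
    if (min(f) < 1L || max(f) > nrow(v))
      return("face indices out of range")
    if (any(f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]))
      return("faces must not repeat a vertex")
  }
  if (!object@representation %in% REPRESENTATION_TAGS)
    return(sprintf("unknown representation tag '%s'", object@representation))
  for (nm in names(object@scalars))
    if (length(object@scalars[[nm]]) != nrow(v))
      return(sprintf("scalar field '%s' has wrong length", nm))
  TRUE
})

#' Construct a SurfaceMesh
#'
#' Degenerate faces (area below \code{1e-12}) are removed with a message,
#' per the load-time contract.
#'
#' @param vertices n x 3 numeric matrix of vertex coordinates.
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @param representation representation tag.
#' @param scalars named list of per-vertex numeric fields.
#' @param dropDegenerate remove zero-area faces (default TRUE).
#' @return A \linkS4class{SurfaceMesh}.
#' @export
SurfaceMesh <- function(vertices, faces,
                        representation = "cartesian",
                        scalars = list(), dropDegenerate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  if (dropDegenerate && nrow(faces) > 0L) {
    a <- triangleAreas(vertices, faces)
    bad <- !is.finite(a) | a < 1e-12
    if (any(bad)) {
      message(sum(bad), " degenerate face(s) removed")
      faces <- faces[!bad, , drop = FALSE]
    }
  }
  new("SurfaceMesh", vertices = vertices, faces = faces,
      representation = representation, scalars = scalars)
}

#' Binary voxel volume
#'
#' @slot data logical 3D array (dim = c(nx, ny, nz)).
#' @slot origin numeric(3); offset of the mesh coordinate frame: a mesh
#'   point p maps to array coordinate p - origin.
#' @export
setClass("BinaryVolume",
  representation(data = "array", origin = "numeric"),
  prototype(origin = c(0, 0, 0)))

setValidity("BinaryVolume", function(object) {
  if (length(dim(object@data)) != 3L) return("data must be a 3D array")
  if (!is.logical(object@data)) return("data must be logical")
  if (any(dim(object@data) < 1L)) return("shape must be strictly positive")
  if (length(object@origin) != 3L) return("origin must be numeric(3)")
  TRUE
})

#' @rdname BinaryVolume-class
#' @param data logical 3D array.
#' @param origin numeric(3) coordinate offset.
#' @export
BinaryVolume <- function(data, origin = c(0, 0, 0)) {
  storage.mode(data) <- "logical"
  new("BinaryVolume", data = data, origin = as.numeric(origin))
}

#' Signed distance volume
#'
#' Euclidean signed distance transform of a binary volume, positive
#' inside the object (so convex surfaces score positive mean curvature).
#'
#' @slot data numeric 3D array.
#' @slot origin numeric(3) frame offset, as in \linkS4class{BinaryVolume}.
#' @export
setClass("SignedDistanceVolume",
  representation(data = "array", origin = "numeric"),
  prototype(origin = c(0, 0, 0)))

#' Mesh topology summary
#'
#' Vertex/edge/face counts, Euler characteristic, genus and boundary
#' structure of a triangle mesh.
#'
#' @slot nVertices,nEdges,nFaces integer counts.
#' @slot euler integer Euler characteristic V - E + F.
#' @slot genus integer genus (NA for non-manifold meshes).
#' @slot boundaryLoops integer number of boundary loops.
#' @slot watertight logical; every edge shared by exactly two faces.
#' @slot manifold logical; no edge with more than two incident faces.
#' @export
setClass("TopologyReport",
  representation(nVertices = "integer", nEdges = "integer",
                 nFaces = "integer", euler = "integer", genus = "integer",
                 boundaryLoops = "integer", watertight = "logical",
                 manifold = "logical"))

#' Spherical parameterization of a genus-0 reference mesh
#'
#' @slot sphere \linkS4class{SurfaceMesh} on the unit sphere, sharing faces
#'   with the reference mesh.
#' @slot reference the genus-0 reference \linkS4class{SurfaceMesh}.
#' @slot history data.frame of per-iteration relaxation diagnostics
#'   (median lambda, lambda IQR, global conformal error, criterion values).
#' @slot stopIteration integer; relaxation iteration finally adopted.
#' @slot status character; "conformal", "relaxed" or "collapsed".
#' @export
setClass("SphereParam",
  representation(sphere = "SurfaceMesh", reference = "SurfaceMesh",
                 history = "data.frame", stopIteration = "integer",
                 status = "character"),
  prototype(stopIteration = 0L, status = "conformal",
            history = data.frame()))

setValidity("SphereParam", function(object) {
  if (!identical(dim(object@sphere@faces), dim(object@reference@faces)))
    return("sphere and reference meshes must share the face list")
  r <- sqrt(rowSums(object@sphere@vertices^2))
  if (max(abs(r - 1)) > 1e-6)
    return("sphere vertices must have unit norm")
  TRUE
})

#' Equirectangular (u,v) lookup grid
#'
#' Bridge between the unit sphere, the 2D plane and topographic space:
#' for every (u,v) pixel it records the matched spherical triangle, its
#' barycentric weights, the pulled-back 3D coordinate of the target mesh
#' and the differential area of the pixel.
#'
#' Rows index the polar angle v in [0, pi] (north at row 1); columns index
#' the azimuth u in [-pi, pi]; the first and last columns are duplicates
#' (seam), so the grid is N x (2N+1).
#'
#' @slot coords numeric array (N, M, 3) of pulled-back 3D coordinates.
#' @slot faceIndex integer matrix (N, M) of matched sphere faces.
#' @slot weights numeric array (N, M, 3) of barycentric weights.
#' @slot dA numeric matrix (N, M) of per-pixel differential areas.
#' @slot rotation proper rotation applied to the sphere before unwrapping.
#' @slot faces face matrix of the sphere mesh the grid was built from.
#' @slot seamDuplicated logical; TRUE when the last column repeats the first.
#' @export
setClass("UVGrid",
  representation(coords = "array", faceIndex = "matrix", weights = "array",
                 dA = "matrix", rotation = "matrix", faces = "matrix",
                 seamDuplicated = "logical"),
  prototype(seamDuplicated = TRUE))

setValidity("UVGrid", function(object) {
  if (length(dim(object@coords)) != 3L || dim(object@coords)[3] != 3L)
    return("coords must be an (N, M, 3) array")
  w <- object@weights
  if (!all(abs(apply(w, c(1, 2), sum) - 1) < 1e-6))
    return("barycentric weights must sum to 1")
  if (min(w) < -1e-8) return("barycentric weights must be nonnegative")
  if (object@seamDuplicated) {
    if (max(abs(object@coords[, 1, ] - object@coords[, dim(object@coords)[2], ])) > 1e-9)
      return("first and last column must be identical when seam is duplicated")
  }
  if (abs(det(object@rotation) - 1) > 1e-9)
    return("rotation must be proper (det = +1)")
  TRUE
})

#' Topographic (d,u,v) coordinate space
#'
#' Lookup volume mapping topographic coordinates (d, v, u) to Cartesian
#' (x, y, z), built by propagating the (u,v)-parameterized reference
#' surface along the signed-distance gradient in steps of \code{alpha}
#' voxels. Depth index 1 corresponds to d = -dIn; the reference shell
#' (d = 0) is at depth index \code{dIn + 1}.
#'
#' @slot coords numeric array (D, N, M, 3); D = dIn + dOut + 1.
#' @slot alpha step size in voxels per depth unit.
#' @slot dIn,dOut number of inward/outward steps.
#' @slot uv the \linkS4class{UVGrid} the space was grown from.
#' @export
setClass("TopographicSpace",
  representation(coords = "array", alpha = "numeric", dIn = "integer",
                 dOut = "integer", uv = "UVGrid"))

setValidity("TopographicSpace", function(object) {
  d <- dim(object@coords)
  if (length(d) != 4L || d[4] != 3L)
    return("coords must be a (D, N, M, 3) array")
  if (d[1] != object@dIn + object@dOut + 1L)
    return("depth dimension must equal dIn + dOut + 1")
  TRUE
})

#' Per-face / per-pixel distortion report
#'
#' Conformal error Q (>= 1, singular-value ratio of the per-element affine
#' map) and area-distortion factor lambda (> 0, ratio of normalized area
#' fractions), with area-weighted global summaries and the stopping
#' criterion aggregates used for area-distortion relaxation.
#'
#' @slot Q per-element conformal error.
#' @slot lambda per-element area-distortion factor.
#' @slot globalQ area-weighted mean conformal error.
#' @slot globalLambda mean area-distortion factor.
#' @slot medianLambda median area-distortion factor.
#' @slot criteria named numeric vector: equiareal_gap, mips, area_mips,
#'   isometric.
#' @slot nInfinite number of collapsed elements excluded from the
#'   aggregates.
#' @export
setClass("DistortionReport",
  representation(Q = "numeric", lambda = "numeric", globalQ = "numeric",
                 globalLambda = "numeric", medianLambda = "numeric",
                 criteria = "numeric", nInfinite = "integer"))

#' Mesh-to-mesh difference metrics
#'
#' @slot chamfer symmetric Chamfer distance (voxels).
#' @slot slicedW1 max-sliced Wasserstein-1 distance (voxels).
#' @slot deltaAreaPct percentage surface-area difference.
#' @slot deltaVolumePct percentage volume difference.
#' @slot projections,repeats sliced-Wasserstein sampling parameters.
#' @slot seed RNG seed used for the projections.
#' @export
setClass("MeshDifference",
  representation(chamfer = "numeric", slicedW1 = "numeric",
                 deltaAreaPct = "numeric", deltaVolumePct = "numeric",
                 projections = "integer", repeats = "integer",
                 seed = "integer"))
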