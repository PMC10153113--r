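#' Accessors for SurfaceMesh and friends
#'
#' @param x object.
#' @param ... unused.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("vertices", function(x, ...) standardGeneric("vertices"))
#' @rdname accessors
#' @export
setMethod("vertices", "SurfaceMesh", function(x, ...) x@vertices)

#' @rdname accessors
#' @export
setGeneric("faces", function(x, ...) standardGeneric("faces"))
#' @rdname accessors
#' @export
setMethod("faces", "SurfaceMesh", function(x, ...) x@faces)

#' @rdname accessors
#' @export
setGeneric("representation", function(x, ...) standardGeneric("representation"))
#' @rdname accessors
#' @export
setMethod("representation", "SurfaceMesh", function(x, ...) x@representation)

#' @rdname accessors
#' @export
setGeneric("nVertices", function(x, ...) standardGeneric("nVertices"))
#' @rdname accessors
#' @export
setMethod("nVertices", "SurfaceMesh", function(x, ...) nrow(x@vertices))

#' @rdname accessors
#' @export
setGeneric("nFaces", function(x, ...) standardGeneric("nFaces"))
#' @rdname accessors
#' @export
setMethod("nFaces", "SurfaceMesh", function(x, ...) nrow(x@faces))

#' @rdname accessors
#' @param name scalar field name.
#' @export
setGeneric("scalarField", function(x, name, ...) standardGeneric("scalarField"))
#' @rdname accessors
#' @export
setMethod("scalarField", "SurfaceMesh", function(x, name, ...) {
  if (!name %in% names(x@scalars)) stop("no scalar field '", name, "'")
  x@scalars[[name]]
})

#' @rdname accessors
#' @param value replacement value.
#' @export
setGeneric("scalarField<-",
           function(x, name, value) standardGeneric("scalarField<-"))
#' @rdname accessors
#' @export
setMethod("scalarField<-", "SurfaceMesh", function(x, name, value) {
  stopifnot(length(value) == nrow(x@vertices))
  x@scalars[[name]] <- as.numeric(value)
  validObject(x)
  x
})

#' @rdname accessors
#' @export
setGeneric("sphereMesh", function(x, ...) standardGeneric("sphereMesh"))
#' @rdname accessors
#' @export
setMethod("sphereMesh", "SphereParam", function(x, ...) x@sphere)

#' @rdname accessors
#' @export
setGeneric("referenceMesh", function(x, ...) standardGeneric("referenceMesh"))
#' @rdname accessors
#' @export
setMethod("referenceMesh", "SphereParam", function(x, ...) x@reference)

#' @rdname accessors
#' @export
setGeneric("relaxationHistory",
           function(x, ...) standardGeneric("relaxationHistory"))
#' @rdname accessors
#' @export
setMethod("relaxationHistory", "SphereParam", function(x, ...) x@history)

#' @rdname accessors
#' @export
setGeneric("volumeData", function(x, ...) standardGeneric("volumeData"))
#' @rdname accessors
#' @export
setMethod("volumeData", "BinaryVolume", function(x, ...) x@data)

#' @rdname accessors
#' @export
setGeneric("volumeOrigin", function(x, ...) standardGeneric("volumeOrigin"))
#' @rdname accessors
#' @export
setMethod("volumeOrigin", "BinaryVolume", function(x, ...) x@origin)

#' @rdname accessors
#' @export
setGeneric("uvCoords", function(x, ...) standardGeneric("uvCoords"))
#' @rdname accessors
#' @export
setMethod("uvCoords", "UVGrid", function(x, ...) x@coords)

#' @rdname accessors
#' @export
setGeneric("differentialArea",
           function(x, ...) standardGeneric("differentialArea"))
#' @rdname accessors
#' @export
setMethod("differentialArea", "UVGrid", function(x, ...) x@dA)

setMethod("show", "SurfaceMesh", function(object) {
  cat(sprintf("SurfaceMesh [%s]: %d vertices, %d faces",
              object@representation, nrow(object@vertices),
              nrow(object@faces)))
  if (length(object@scalars))
    cat(sprintf("; fields: %s", paste(names(object@scalars), collapse = ", ")))
  cat("\n")
})

setMethod("show", "BinaryVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("BinaryVolume %dx%dx%d, %d foreground voxels\n",
              d[1], d[2], d[3], sum(object@data)))
})

setMethod("show", "TopologyReport", function(object) {
  cat(sprintf(
    "TopologyReport: V=%d E=%d F=%d chi=%d genus=%s boundaries=%d %s%s\n",
    object@nVertices, object@nEdges, object@nFaces, object@euler,
    ifelse(is.na(object@genus), "NA", object@genus), object@boundaryLoops,
    if (object@watertight) "watertight" else "open",
    if (object@manifold) "" else " NON-MANIFOLD"))
})

setMethod("show", "SphereParam", function(object) {
  cat(sprintf("SphereParam [%s]: %d vertices, stop iteration %d\n",
              object@status, nrow(object@sphere@vertices),
              object@stopIteration))
})

setMethod("show", "UVGrid", function(object) {
  d <- dim(object@coords)
  cat(sprintf("UVGrid %d x %d (seam %s), total dA %.1f\n", d[1], d[2],
              if (object@seamDuplicated) "duplicated" else "dropped",
              sum(object@dA)))
})

setMethod("show", "TopographicSpace", function(object) {
  d <- dim(object@coords)
  cat(sprintf(
    "TopographicSpace D=%d (dIn=%d, dOut=%d) x %d x %d, alpha=%.2f\n",
    d[1], object@dIn, object@dOut, d[2], d[3], object@alpha))
})

setMethod("show", "DistortionReport", function(object) {
  cat(sprintf(
    "DistortionReport: global Q=%.4f, mean lambda=%.4f, median lambda=%.4f (%d collapsed)\n",
    object@globalQ, object@globalLambda, object@medianLambda,
    object@nInfinite))
})

setMethod("show", "MeshDifference", function(object) {
  cat(sprintf(
    "MeshDifference: CD=%.3f, SW1=%.3f, dA=%.2f%%, dV=%.2f%%\n",
    object@chamfer, object@slicedW1, object@deltaAreaPct,
    object@deltaVolumePct))
})
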