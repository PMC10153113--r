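# Mesh, volume and report I/O: OBJ, ascii PLY (with per-vertex scalar
# properties), multi-page TIFF volumes (z,y,x page order) and JSON
# serialization of reports.

#' Read a triangle mesh from OBJ or PLY
#'
#' @param path file path (.obj or .ply; PLY ascii or binary_little_endian).
#' @param representation tag for the result.
#' @return \linkS4class{SurfaceMesh}; PLY per-vertex properties beyond
#'   x/y/z become scalar fields.
#' @export
readMesh <- function(path, representation = "cartesian") {
  ext <- tolower(tools::file_ext(path))
  if (ext == "obj") {
    ln <- readLines(path)
    vl <- ln[startsWith(ln, "v ")]
    fl <- ln[startsWith(ln, "f ")]
    V <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vl)), "\\s+"),
                               function(x) as.numeric(x[1:3])))
    F <- do.call(rbind, lapply(strsplit(trimws(sub("^f", "", fl)), "\\s+"),
                               function(x) as.integer(sub("/.*", "", x[1:3]))))
    return(SurfaceMesh(V, F, representation = representation))
  }
  if (ext == "ply") return(readPLY(path, representation))
  stop("unsupported mesh format: ", ext)
}

#' Write a triangle mesh to OBJ or ascii PLY
#'
#' @param mesh \linkS4class{SurfaceMesh}.
#' @param path output path; the extension picks the format. PLY output
#'   stores the scalar fields as extra float vertex properties.
#' @return invisibly, the path.
#' @export
writeMesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  V <- mesh@vertices; F <- mesh@faces
  if (ext == "obj") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("v %.8g %.8g %.8g", V[, 1], V[, 2], V[, 3]), con)
    writeLines(sprintf("f %d %d %d", F[, 1], F[, 2], F[, 3]), con)
  } else if (ext == "ply") {
    con <- file(path, "w")
    on.exit(close(con))
    extras <- names(mesh@scalars)
    hdr <- c("ply", "format ascii 1.0",
             sprintf("element vertex %d", nrow(V)),
             "property float x", "property float y", "property float z",
             sprintf("property float %s", extras),
             sprintf("element face %d", nrow(F)),
             "property list uchar int vertex_indices", "end_header")
    writeLines(hdr, con)
    dat <- cbind(V, do.call(cbind, c(mesh@scalars, list())))
    writeLines(apply(format(dat, digits = 8, trim = TRUE,
                            scientific = FALSE), 1, paste,
                     collapse = " "), con)
    writeLines(sprintf("3 %d %d %d", F[, 1] - 1L, F[, 2] - 1L,
                       F[, 3] - 1L), con)
  } else stop("unsupported mesh format: ", ext)
  invisible(path)
}

readPLY <- function(path, representation = "cartesian") {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character(0)
  repeat {
    l <- readLines(con, 1)
    hdr <- c(hdr, l)
    if (l == "end_header") break
  }
  fmt <- sub("^format ", "", grep("^format", hdr, value = TRUE))
  nV <- as.integer(sub(".*vertex ", "",
                       grep("^element vertex", hdr, value = TRUE)))
  nF <- as.integer(sub(".*face ", "",
                       grep("^element face", hdr, value = TRUE)))
  # vertex property names, in order
  vstart <- grep("^element vertex", hdr)
  fstart <- grep("^element face", hdr)
  props <- hdr[(vstart + 1):(fstart - 1)]
  props <- props[startsWith(props, "property")]
  pnames <- vapply(strsplit(props, "\\s+"), function(x) x[3], "")
  if (startsWith(fmt, "ascii")) {
    vl <- readLines(con, nV)
    vdat <- matrix(as.numeric(unlist(strsplit(trimws(vl), "\\s+"))),
                   nV, length(pnames), byrow = TRUE)
    fl <- readLines(con, nF)
    F <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), function(x)
      as.integer(x[2:4]) + 1L))
  } else if (startsWith(fmt, "binary_little_endian")) {
    ptypes <- vapply(strsplit(props, "\\s+"), function(x) x[2], "")
    if (!all(ptypes %in% c("float", "float32")))
      stop("binary PLY reader supports float32 vertex properties only")
    vdat <- matrix(readBin(con, "double", nV * length(pnames), size = 4,
                           endian = "little"),
                   nV, length(pnames), byrow = TRUE)
    F <- matrix(0L, nF, 3)
    for (i in seq_len(nF)) {
      cnt <- readBin(con, "integer", 1, size = 1, signed = FALSE)
      idx <- readBin(con, "integer", cnt, size = 4, endian = "little")
      F[i, ] <- idx[1:3] + 1L
    }
  } else stop("unsupported PLY format: ", fmt)
  xyz <- match(c("x", "y", "z"), pnames)
  extra <- setdiff(seq_along(pnames), xyz)
  scal <- stats::setNames(lapply(extra, function(i) vdat[, i]),
                          pnames[extra])
  SurfaceMesh(vdat[, xyz, drop = FALSE], F,
              representation = representation, scalars = scal)
}

#' Read/write volumes as multi-page TIFF
#'
#' Pages are z-slices in (y, x) orientation, matching the (z, y, x) axis
#' order of microscopy stacks; in memory volumes are (x, y, z) arrays.
#'
#' @param vol 3D numeric/logical array (x, y, z).
#' @param path file path.
#' @return \code{readVolumeTIFF}: 3D numeric array.
#' @export
writeVolumeTIFF <- function(vol, path) {
  d <- dim(vol)
  mx <- max(abs(as.numeric(vol)), 1e-12)
  pages <- lapply(seq_len(d[3]), function(k) t(vol[, , k]) / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

#' @rdname writeVolumeTIFF
#' @export
readVolumeTIFF <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- dim(pages[[1]])
  out <- array(0, c(d[2], d[1], length(pages)))
  for (k in seq_along(pages)) out[, , k] <- t(pages[[k]])
  out
}

#' Serialize a report object to JSON
#'
#' @param x a \linkS4class{TopologyReport}, \linkS4class{DistortionReport},
#'   \linkS4class{MeshDifference} or data.frame.
#' @param path optional output path; otherwise the JSON string is
#'   returned.
#' @param perElement include per-face/per-pixel vectors (large).
#' @return JSON string (invisibly when written to a file).
#' @export
reportToJSON <- function(x, path = NULL, perElement = FALSE) {
  lst <- if (is.data.frame(x)) x else {
    sl <- methods::slotNames(class(x))
    if (!perElement) sl <- setdiff(sl, c("Q", "lambda"))
    stats::setNames(lapply(sl, methods::slot, object = x), sl)
  }
  js <- jsonlite::toJSON(lst, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
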