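# Low-level triangle mesh helpers shared across modules.

#' Per-face areas of a triangle mesh
#' @param V vertex matrix.
#' @param F face index matrix.
#' @return numeric vector of face areas.
#' @export
triangleAreas <- function(V, F) {
  e1 <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  e2 <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Total surface area of a mesh
#' @param mesh SurfaceMesh.
#' @return total area.
#' @export
surfaceArea <- function(mesh) sum(triangleAreas(mesh@vertices, mesh@faces))

#' Signed enclosed volume of a closed mesh (divergence theorem)
#' @param mesh SurfaceMesh with outward-oriented faces.
#' @return signed volume; positive for outward orientation.
#' @export
meshVolume <- function(mesh) {
  V <- mesh@vertices; F <- mesh@faces
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  cc <- V[F[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
      a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
      a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
}

# Unnormalized face normals (cross products); rows of zero length flag
# degenerate faces.
faceNormalsRaw <- function(V, F) {
  e1 <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  e2 <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
        e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
        e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
}

#' Unit face normals
#' @param mesh SurfaceMesh.
#' @return nFaces x 3 matrix.
#' @export
faceNormals <- function(mesh) {
  n <- faceNormalsRaw(mesh@vertices, mesh@faces)
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

#' Angle-weighted unit vertex normals
#' @param mesh SurfaceMesh.
#' @return nVertices x 3 matrix.
#' @export
vertexNormals <- function(mesh) {
  V <- mesh@vertices; F <- mesh@faces
  fn <- faceNormals(mesh)
  ang <- interiorAngles(V, F)  # nFaces x 3, angle at corner 1..3
  out <- matrix(0, nrow(V), 3)
  for (c in 1:3) {
    idx <- F[, c]
    w <- ang[, c]
    out[, 1] <- out[, 1] + unname(tapplySum(w * fn[, 1], idx, nrow(V)))
    out[, 2] <- out[, 2] + unname(tapplySum(w * fn[, 2], idx, nrow(V)))
    out[, 3] <- out[, 3] + unname(tapplySum(w * fn[, 3], idx, nrow(V)))
  }
  len <- sqrt(rowSums(out^2))
  len[len == 0] <- 1
  out / len
}

# Fast grouped sum into a vector of length n.
tapplySum <- function(x, idx, n) {
  out <- numeric(n)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

# Interior angles of every face at its three corners.
interiorAngles <- function(V, F) {
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  cc <- V[F[, 3], , drop = FALSE]
  lab <- sqrt(rowSums((a - b)^2))
  lbc <- sqrt(rowSums((b - cc)^2))
  lca <- sqrt(rowSums((cc - a)^2))
  clamp <- function(x) pmin(1, pmax(-1, x))
  A <- acos(clamp((lab^2 + lca^2 - lbc^2) / (2 * lab * lca)))
  B <- acos(clamp((lab^2 + lbc^2 - lca^2) / (2 * lab * lbc)))
  C <- pi - A - B
  cbind(A, B, C)
}

# Undirected edge table: matrix with columns v1 < v2, plus per-face
# half-edge bookkeeping.
meshEdges <- function(F) {
  he <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  key <- paste(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
  uk <- !duplicated(key)
  list(edges = cbind(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))[uk, ,
                                                                     drop = FALSE],
       halfedges = he,
       key = key,
       face = rep(seq_len(nrow(F)), 3L))
}

#' Midpoint (1-to-4) subdivision
#' @param mesh SurfaceMesh.
#' @param times number of rounds.
#' @return subdivided SurfaceMesh.
#' @export
subdivideMidpoint <- function(mesh, times = 1L) {
  V <- mesh@vertices; F <- mesh@faces
  for (t in seq_len(times)) {
    em <- meshEdges(F)
    E <- em$edges
    mid <- (V[E[, 1], , drop = FALSE] + V[E[, 2], , drop = FALSE]) / 2
    ekey <- paste(E[, 1], E[, 2])
    eid <- stats::setNames(seq_len(nrow(E)) + nrow(V), ekey)
    k12 <- eid[paste(pmin(F[, 1], F[, 2]), pmax(F[, 1], F[, 2]))]
    k23 <- eid[paste(pmin(F[, 2], F[, 3]), pmax(F[, 2], F[, 3]))]
    k31 <- eid[paste(pmin(F[, 3], F[, 1]), pmax(F[, 3], F[, 1]))]
    F <- rbind(cbind(F[, 1], k12, k31),
               cbind(F[, 2], k23, k12),
               cbind(F[, 3], k31, k23),
               cbind(k12, k23, k31))
    storage.mode(F) <- "integer"
    V <- rbind(V, mid)
  }
  SurfaceMesh(V, F, representation = mesh@representation,
              dropDegenerate = FALSE)
}

#' Mean edge length
#' @param mesh SurfaceMesh.
#' @return mean undirected edge length.
#' @export
meanEdgeLength <- function(mesh) {
  E <- meshEdges(mesh@faces)$edges
  mean(sqrt(rowSums((mesh@vertices[E[, 1], , drop = FALSE] -
                     mesh@vertices[E[, 2], , drop = FALSE])^2)))
}

# Orient all faces consistently by BFS over the face adjacency graph, then
# flip globally so the signed volume is positive (outward normals).
orientFaces <- function(V, F) {
  m <- nrow(F)
  if (m == 0L) return(F)
  he <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  hf <- rep(seq_len(m), 3L)
  a <- pmin(he[, 1], he[, 2]); b <- pmax(he[, 1], he[, 2])
  key <- paste(a, b)
  ord <- order(key, method = "radix")
  # consecutive equal keys = the two half-edges of a shared edge
  pairIdx <- which(key[ord][-1] == key[ord][-length(ord)])
  i1 <- ord[pairIdx]; i2 <- ord[pairIdx + 1L]
  f1 <- hf[i1]; f2 <- hf[i2]
  same <- he[i1, 1] == he[i2, 1]  # same direction => inconsistent winding
  # CSR adjacency over faces
  src <- c(f1, f2); dst <- c(f2, f1); sm <- c(same, same)
  o <- order(src, method = "radix")
  src <- src[o]; dst <- dst[o]; sm <- sm[o]
  starts <- c(0L, cumsum(tabulate(src, m)))
  flip <- rep(NA, m)
  stack <- integer(m)
  for (seed in seq_len(m)) {
    if (!is.na(flip[seed])) next
    flip[seed] <- FALSE
    top <- 1L; stack[1L] <- seed
    while (top > 0L) {
      f <- stack[top]; top <- top - 1L
      if (starts[f + 1L] <= starts[f]) next
      for (e in (starts[f] + 1L):starts[f + 1L]) {
        other <- dst[e]
        if (is.na(flip[other])) {
          flip[other] <- xor(flip[f], sm[e])
          top <- top + 1L; stack[top] <- other
        }
      }
    }
  }
  F2 <- F
  F2[flip, c(2, 3)] <- F[flip, c(3, 2)]
  vol <- meshVolume(new("SurfaceMesh", vertices = V, faces = F2,
                        representation = "cartesian", scalars = list()))
  if (vol < 0) F2 <- F2[, c(1, 3, 2)]
  storage.mode(F2) <- "integer"
  F2
}

#' Extract submeshes
#'
#' \code{submeshByFaces} keeps the listed faces and drops unreferenced
#' vertices; \code{submeshByVertices} keeps faces whose three corners all
#' belong to the vertex set.
#'
#' @param mesh \linkS4class{SurfaceMesh}.
#' @param keep face indices to keep.
#' @return list with \code{mesh} and \code{vertexMap} (old indices of the
#'   kept vertices).
#' @export
submeshByFaces <- function(mesh, keep) {
  F <- mesh@faces[keep, , drop = FALSE]
  used <- sort(unique(as.vector(F)))
  map <- integer(nrow(mesh@vertices))
  map[used] <- seq_along(used)
  F2 <- matrix(map[F], ncol = 3)
  storage.mode(F2) <- "integer"
  scal <- lapply(mesh@scalars, function(s) s[used])
  list(mesh = new("SurfaceMesh", vertices = mesh@vertices[used, , drop = FALSE],
                  faces = F2, representation = mesh@representation,
                  scalars = scal),
       vertexMap = used)
}

#' @rdname submeshByFaces
#' @param vset vertex indices.
#' @export
submeshByVertices <- function(mesh, vset) {
  inset <- logical(nrow(mesh@vertices))
  inset[vset] <- TRUE
  keep <- inset[mesh@faces[, 1]] & inset[mesh@faces[, 2]] &
    inset[mesh@faces[, 3]]
  submeshByFaces(mesh, which(keep))
}

#' Largest connected component of a mesh
#' @param mesh SurfaceMesh.
#' @return SurfaceMesh restricted to its largest vertex-connected component.
#' @export
largestComponent <- function(mesh) {
  F <- mesh@faces
  E <- rbind(F[, 1:2], F[, 2:3], F[, c(3, 1)])  # dupes are harmless here
  lab <- cpp_graph_components(nrow(mesh@vertices), E)
  big <- as.integer(names(which.max(table(lab))))
  submeshByVertices(mesh, which(lab == big))$mesh
}

# Vertex connected-component labels of a sub-vertex-set on the mesh graph.
vertexComponents <- function(mesh, vset) {
  inset <- logical(nrow(mesh@vertices)); inset[vset] <- TRUE
  E <- meshEdges(mesh@faces)$edges
  E <- E[inset[E[, 1]] & inset[E[, 2]], , drop = FALSE]
  lab <- cpp_graph_components(nrow(mesh@vertices), E)
  lab[!inset] <- 0L
  # relabel components restricted to vset contiguously
  ids <- unique(lab[inset])
  match(lab, ids)
}

#' Ordered boundary loops of a face matrix
#'
#' Boundary edges (single incident face) are chained into ordered loops
#' of vertex indices.
#'
#' @param F face index matrix.
#' @return list of integer vectors, one per loop.
#' @export
boundaryLoops <- function(F) {
  he <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  key <- paste(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
  cnt <- table(key)
  bnd <- he[cnt[key] == 1L, , drop = FALSE]
  if (nrow(bnd) == 0L) return(list())
  starts <- bnd[, 1]
  nxt <- integer(max(bnd))
  nxt[bnd[, 1]] <- bnd[, 2]
  visited <- logical(max(bnd))
  loops <- list()
  for (s in starts) {
    if (visited[s]) next
    loop <- integer(0)
    cur <- s
    repeat {
      loop <- c(loop, cur)
      visited[cur] <- TRUE
      cur <- if (cur <= length(nxt)) nxt[cur] else 0L
      if (cur == 0L || visited[cur]) break
    }
    loops[[length(loops) + 1L]] <- loop
  }
  loops
}
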