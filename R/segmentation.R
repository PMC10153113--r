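# Unsupervised topography-guided protrusion segmentation: ALS reference
# surface, height-based binary segmentation, curvature-seeded instance
# segmentation with affinity diffusion, watershed refinement, and
# depth propagation / volumization.

# ---- small shared helpers -------------------------------------------------

# Barycentric per-vertex areas.
vertexAreas <- function(mesh) {
  a <- triangleAreas(mesh@vertices, mesh@faces)
  n <- nrow(mesh@vertices)
  out <- numeric(n)
  for (c in 1:3) out <- out + tapplySum(a / 3, mesh@faces[, c], n)
  out
}

# Upper threshold of 3-class Otsu (exhaustive over a 128-bin histogram).
otsuUpperThreshold <- function(x, nbins = 128L) {
  x <- x[is.finite(x)]
  br <- seq(min(x), max(x), length.out = nbins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins)
  p <- h / sum(h)
  mid <- (br[-1] + br[-length(br)]) / 2
  cw <- cumsum(p); cm <- cumsum(p * mid)
  total <- cm[nbins]
  best <- -Inf; t1b <- 1L; t2b <- 2L
  for (t1 in 1:(nbins - 2L)) {
    w1 <- cw[t1]; m1 <- cm[t1]
    if (w1 <= 0) next
    for (t2 in (t1 + 1L):(nbins - 1L)) {
      w2 <- cw[t2] - w1; w3 <- 1 - cw[t2]
      if (w2 <= 0 || w3 <= 0) next
      m2 <- cm[t2] - m1; m3 <- total - cm[t2]
      v <- m1^2 / w1 + m2^2 / w2 + m3^2 / w3
      if (v > best) { best <- v; t1b <- t1; t2b <- t2 }
    }
  }
  mid[t2b]
}

# Components of a vertex subset over the sparsity pattern of an affinity
# matrix (or mesh edges); returns labels (0 outside subset).
affinityComponents <- function(A, subset) {
  n <- nrow(A)
  T3 <- Matrix::mat2triplet(A)
  keep <- T3$i < T3$j & subset[T3$i] & subset[T3$j]
  E <- cbind(T3$i[keep], T3$j[keep])
  storage.mode(E) <- "integer"
  lab <- cpp_graph_components(n, E)
  lab[!subset] <- 0L
  ids <- setdiff(unique(lab), 0L)
  out <- integer(n)
  out[subset] <- match(lab[subset], ids)
  out
}

#' Graph label spreading
#'
#' Semi-supervised diffusion of seed labels through a symmetrically
#' normalized affinity matrix: \code{F <- clamp * S F + (1-clamp) * Y}.
#' Optionally the foreground probability is re-binarized at
#' \code{rebinarize} at the start of every iteration (two-class mode).
#'
#' @param A sparse symmetric affinity (diagonal included).
#' @param labels integer seed labels (0 = background class when
#'   \code{backgroundClass}, else unlabeled).
#' @param iterations diffusion iterations.
#' @param clamp clamping ratio (weight of the diffused term).
#' @param rebinarize probability threshold for two-class re-binarization
#'   per iteration (NULL: none).
#' @param backgroundClass treat label 0 as an explicit class.
#' @return list: \code{labels} (argmax, 0 where no mass), \code{prob}
#'   (matrix of class probabilities).
#' @export
labelSpreading <- function(A, labels, iterations = 10L, clamp = 0.99,
                           rebinarize = NULL, backgroundClass = TRUE) {
  n <- nrow(A)
  dg <- Matrix::rowSums(A)
  Dh <- Matrix::Diagonal(n, 1 / sqrt(pmax(dg, 1e-12)))
  S <- Dh %*% A %*% Dh
  classes <- sort(unique(labels))
  if (!backgroundClass) classes <- setdiff(classes, 0L)
  K <- length(classes)
  Y <- matrix(0, n, K)
  for (k in seq_len(K)) Y[labels == classes[k], k] <- 1
  Fm <- Y
  for (it in seq_len(iterations)) {
    if (!is.null(rebinarize) && K == 2L) {
      tot <- rowSums(Fm)
      p <- ifelse(tot > 0, Fm[, 2] / pmax(tot, 1e-12), 0)
      Fm <- matrix(0, n, 2)
      Fm[p > rebinarize, 2] <- 1
      Fm[p <= rebinarize, 1] <- 1
    }
    Fm <- as.matrix(clamp * (S %*% Fm) + (1 - clamp) * Y)
  }
  mx <- apply(Fm, 1, max)
  arg <- max.col(Fm, ties.method = "first")
  out <- ifelse(mx > 0, classes[arg], 0L)
  list(labels = as.integer(out), prob = Fm, classes = classes)
}

#' Combined geodesic-distance / convexity affinity matrix
#'
#' Sparse over the mesh one-ring. The distance component is
#' \code{exp(-D^2 / (2 mu(D)^2))} with D the Euclidean edge length; the
#' convexity component applies the same kernel to the cosine distance
#' \code{(1 - cos theta)/2} of the vertex-normal dihedral angles.
#' \code{mu(D)} is the mean over the included off-diagonal entries.
#' Diagonal entries are 1.
#'
#' @param mesh \linkS4class{SurfaceMesh}.
#' @param gamma mixing weight of the distance component in [0, 1].
#' @return sparse symmetric affinity matrix.
#' @export
buildAffinity <- function(mesh, gamma = 0.9) {
  stopifnot(gamma >= 0, gamma <= 1)
  E <- meshEdges(mesh@faces)$edges
  n <- nrow(mesh@vertices)
  dd <- sqrt(rowSums((mesh@vertices[E[, 1], , drop = FALSE] -
                      mesh@vertices[E[, 2], , drop = FALSE])^2))
  muD <- mean(dd)
  aDist <- exp(-dd^2 / (2 * muD^2))
  Nv <- vertexNormals(mesh)
  cosTh <- rowSums(Nv[E[, 1], , drop = FALSE] * Nv[E[, 2], , drop = FALSE])
  dConv <- (1 - cosTh) / 2
  muC <- mean(dConv)
  aConv <- if (muC > 0) exp(-dConv^2 / (2 * muC^2)) else rep(1, length(dConv))
  w <- gamma * aDist + (1 - gamma) * aConv
  Matrix::sparseMatrix(i = c(E[, 1], E[, 2], seq_len(n)),
                       j = c(E[, 2], E[, 1], seq_len(n)),
                       x = c(w, w, rep(1, n)), dims = c(n, n))
}

# ---- reference surface / height -------------------------------------------

#' Height image of a topographic binary volume
#'
#' For every (u,v) column the value is the top d-index of the longest
#' contiguous foreground run (so the image is a height map of the
#' outermost coherent surface). Columns without foreground get 0.
#'
#' @param topoBinary 3D array (d, v, u).
#' @return numeric matrix (v, u); attribute \code{"n_empty"} counts empty
#'   columns.
#' @export
uvHeightImage <- function(topoBinary) {
  d <- dim(topoBinary)
  if (!any(topoBinary > 0.5)) stop("empty topographic binary")
  cur <- matrix(0, d[2], d[3])
  best <- matrix(0, d[2], d[3])
  top <- matrix(0, d[2], d[3])
  for (k in seq_len(d[1])) {
    fg <- matrix(topoBinary[k, , ] > 0.5, d[2], d[3])
    cur <- (cur + 1) * fg
    upd <- cur > best
    best[upd] <- cur[upd]
    top[upd] <- k
  }
  attr(top, "n_empty") <- sum(best == 0)
  top
}

# block-mean downsampling by an integer factor (edge blocks partial)
downsampleMean <- function(img, f) {
  nr <- nrow(img); nc <- ncol(img)
  ri <- ceiling(seq_len(nr) / f); ci <- ceiling(seq_len(nc) / f)
  num <- rowsum(t(rowsum(img, ri)), ci)
  cnt <- outer(tabulate(ci), tabulate(ri))
  t(num / cnt)
}

# bilinear resize to (nr, nc)
bilinearResize <- function(img, nr, nc) {
  sr <- nrow(img); sc <- ncol(img)
  rows <- if (nr == 1) 1 else seq(1, sr, length.out = nr)
  cols <- if (nc == 1) 1 else seq(1, sc, length.out = nc)
  P <- cbind(rep(rows, times = nc), rep(cols, each = nr), 1)
  v <- cpp_trilinear(as.numeric(img), sr, sc, 1L, P, 0)$values
  matrix(v, nr, nc)
}

#' Asymmetric least squares baseline surface
#'
#' 2D adaptation of the asymmetric least squares (ALS) baseline: the
#' image is downsampled, then iteratively fit by penalized weighted least
#' squares \code{(W + lambda * t(L) L) z = W y} with a 5-point Laplacian
#' penalty and asymmetric weights (\code{p} above the current baseline,
#' \code{1-p} below), and resized back.
#'
#' @param height 2D numeric image (e.g. \code{\link{uvHeightImage}}).
#' @param p asymmetry in (0, 1); small p pulls the baseline under peaks.
#' @param lambdaReg Laplacian penalty weight.
#' @param iterations reweighting iterations.
#' @param downsample integer downsampling factor.
#' @return baseline image of the input size.
#' @export
alsBaseline <- function(height, p = 0.25, lambdaReg = 1, iterations = 10L,
                        downsample = 8L) {
  if (p <= 0 || p >= 1) stop("p must be in (0,1)")
  stopifnot(all(is.finite(height)))
  y <- if (downsample > 1L) downsampleMean(height, downsample) else height
  nr <- nrow(y); nc <- ncol(y)
  n <- nr * nc
  idx <- matrix(seq_len(n), nr, nc)
  ii <- c(); jj <- c(); xx <- c()
  addN <- function(a, b) {
    ii <<- c(ii, a); jj <<- c(jj, b); xx <<- c(xx, rep(1, length(a)))
  }
  addN(as.vector(idx[-1, ]), as.vector(idx[-nr, ]))
  addN(as.vector(idx[-nr, ]), as.vector(idx[-1, ]))
  addN(as.vector(idx[, -1]), as.vector(idx[, -nc]))
  addN(as.vector(idx[, -nc]), as.vector(idx[, -1]))
  Adj <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  L <- Adj - Matrix::Diagonal(n, Matrix::rowSums(Adj))
  LtL <- Matrix::crossprod(L)
  yv <- as.numeric(y)
  z <- yv
  for (it in seq_len(iterations)) {
    w <- ifelse(yv > z, p, 1 - p)
    A <- Matrix::Diagonal(n, w) + lambdaReg * LtL
    z <- as.numeric(Matrix::solve(A, w * yv))
  }
  zi <- matrix(z, nr, nc)
  if (downsample > 1L) bilinearResize(zi, nrow(height), ncol(height))
  else zi
}

#' Protrusion height of a topographic mesh
#'
#' \code{h = d - d_ref}: the depth coordinate of every vertex minus the
#' reference baseline sampled bilinearly at the vertex's (v,u) position.
#'
#' @param topoMesh \linkS4class{SurfaceMesh} with tag "topographic"
#'   (columns d, v, u).
#' @param dRef baseline image (rows v, cols u); a scalar 0 uses the flat
#'   d = 0 plane.
#' @return list: \code{h} per-vertex heights, \code{dRef}.
#' @export
protrusionHeight <- function(topoMesh, dRef = 0) {
  stopifnot(topoMesh@representation == "topographic")
  d <- topoMesh@vertices[, 1]
  if (is.matrix(dRef)) {
    # clamp to the image domain: padded meshing leaves vertices a
    # fraction of a pixel outside it
    P <- cbind(pmin(pmax(topoMesh@vertices[, 2], 1), nrow(dRef)),
               pmin(pmax(topoMesh@vertices[, 3], 1), ncol(dRef)), 1)
    ref <- cpp_trilinear(as.numeric(dRef), nrow(dRef), ncol(dRef), 1L, P,
                         0)$values
  } else ref <- rep(dRef, length(d))
  list(h = d - ref, dRef = dRef)
}

# ---- binary & instance segmentation ---------------------------------------

#' Topography-guided binary protrusion segmentation
#'
#' Seeds are vertices with height at or above the mean height; seed
#' components with Cartesian area below \code{minSeedArea} are removed;
#' two-class label spreading (20 iterations, clamp 0.99, re-binarized at
#' 0.25 each iteration) diffuses the segmentation; final components below
#' \code{minArea} are removed. A flat surface (mean height below 0.5
#' voxel and 95th percentile below 2 voxels) yields an empty
#' segmentation with a warning.
#'
#' @param h per-vertex protrusion heights.
#' @param A affinity matrix (\code{\link{buildAffinity}}).
#' @param areas per-vertex Cartesian areas (voxel^2).
#' @param minSeedArea,minArea area filters (voxel^2).
#' @param iterations,clamp,threshold label-spreading parameters.
#' @param hbar seed threshold; defaults to \code{mean(h)} (the pipeline
#'   passes the mean over interior vertices, excluding domain-cut walls).
#' @param flatHbar,flatQ95 flat-surface guard: with the mean height below
#'   \code{flatHbar} and the 95th percentile below \code{flatQ95} voxels
#'   the segmentation is declared empty.
#' @return integer vector: 1 = protrusion, 0 = cortex.
#' @export
binarySegment <- function(h, A, areas, minSeedArea = 200, minArea = 500,
                          iterations = 20L, clamp = 0.99,
                          threshold = 0.25, hbar = NULL,
                          flatHbar = 0.5, flatQ95 = 2) {
  n <- length(h)
  if (is.null(hbar)) hbar <- mean(h)
  if (hbar < flatHbar && stats::quantile(h, 0.95) < flatQ95) {
    warning("surface is flat; empty segmentation")
    return(integer(n))
  }
  seed <- h >= hbar
  comp <- affinityComponents(A, seed)
  if (max(comp) > 0) {
    aComp <- tapplySum(areas[comp > 0], comp[comp > 0], max(comp))
    seed <- comp > 0 & comp %in% which(aComp >= minSeedArea)
  }
  if (!any(seed)) return(integer(n))
  ls <- labelSpreading(A, as.integer(seed), iterations = iterations,
                       clamp = clamp, rebinarize = threshold)
  tot <- rowSums(ls$prob)
  fg <- ifelse(tot > 0, ls$prob[, 2] / pmax(tot, 1e-12), 0) > threshold
  comp <- affinityComponents(A, fg)
  if (max(comp) > 0) {
    aComp <- tapplySum(areas[comp > 0], comp[comp > 0], max(comp))
    fg <- comp > 0 & comp %in% which(aComp >= minArea)
  }
  as.integer(fg)
}

# ball morphology on 3D logical arrays via the distance transform
dilateBall <- function(fg, r) {
  d <- dim(fg)
  array(cpp_edt3d(fg, d[1], d[2], d[3]) <= r, d)
}
erodeBall <- function(fg, r) {
  d <- dim(fg)
  array(cpp_edt3d(!fg, d[1], d[2], d[3]) > r, d)
}

# expand integer labels into the background by `steps` 6-neighborhood
# rounds (nearest-label growth)
expandLabels3D <- function(lab, steps = 3L) {
  d <- dim(lab)
  for (s in seq_len(steps)) {
    out <- lab
    for (ax in 1:3) for (by in c(-1L, 1L)) {
      idx <- lapply(d, seq_len)
      idx[[ax]] <- pmin(pmax(idx[[ax]] + by, 1L), d[ax])
      nb <- lab[idx[[1]], idx[[2]], idx[[3]]]
      take <- out == 0L & nb > 0L
      out[take] <- nb[take]
    }
    lab <- out
  }
  lab
}

#' Curvature-seeded instance segmentation of protrusions
#'
#' High-curvature protrusion tips are identified by clustering the
#' smoothed topographic mean curvature over surface-shell voxels (k-means
#' with a sigma = 1 feature for blebs/filopodia; a Gaussian mixture over
#' sigma = 1,3,5 multi-scale features for lamellipodia; 3 classes, the
#' class with the highest mean curvature kept). Connected components
#' become seed labels, are expanded by 3 voxels, transferred to the
#' topographic mesh, intersected with the binary segmentation, diffused
#' by label spreading (10 iterations, clamp 0.99, no re-binarization) and
#' finally masked by the binary segmentation.
#'
#' @param topoH 3D mean-curvature volume (d, v, u), e.g. from the signed
#'   distance transform of \code{topoBinary}.
#' @param topoBinary 3D logical array.
#' @param mode \code{"bleb_filopodia"} or \code{"lamellipodia"}.
#' @param binarySeg per-vertex binary segmentation of \code{topoMesh}.
#' @param A affinity matrix on \code{topoMesh}.
#' @param topoMesh topographic \linkS4class{SurfaceMesh}.
#' @param areas per-vertex Cartesian areas.
#' @param minComponentVoxels minimum seed component size (voxels).
#' @param minLabelArea minimum Cartesian area of a transferred label.
#' @param maxSample voxels sampled for the clusterer.
#' @param poleMargin rows next to the two polar image rows excluded from
#'   seeding (the equirectangular poles are coordinate singularities
#'   where the topographic metric degenerates; the unwrapping axis is
#'   chosen so protrusions avoid them).
#' @param seed RNG seed for the voxel sampling.
#' @return integer per-vertex instance labels (0 = background).
#' @export
instanceSegment <- function(topoH, topoBinary,
                            mode = c("bleb_filopodia", "lamellipodia"),
                            binarySeg, A, topoMesh, areas,
                            minComponentVoxels = 500L, minLabelArea = 100,
                            maxSample = 10000L, poleMargin = 3L,
                            seed = 1L) {
  mode <- match.arg(mode)
  d <- dim(topoBinary)
  fg <- array(topoBinary > 0.5, d)
  shell <- dilateBall(fg, 2) & !erodeBall(fg, 2)
  if (poleMargin > 0L) {
    shell[, seq_len(min(poleMargin, d[2])), ] <- FALSE
    shell[, seq(max(1L, d[2] - poleMargin + 1L), d[2]), ] <- FALSE
  }
  idxShell <- which(shell)
  if (length(idxShell) < 10L) return(integer(nrow(topoMesh@vertices)))
  smooth1 <- array(cpp_gauss3d(as.numeric(topoH), d[1], d[2], d[3], 1), d)
  if (mode == "lamellipodia") {
    s3 <- array(cpp_gauss3d(as.numeric(topoH), d[1], d[2], d[3], 3), d)
    s5 <- array(cpp_gauss3d(as.numeric(topoH), d[1], d[2], d[3], 5), d)
    feat <- cbind(smooth1[idxShell], s3[idxShell], s5[idxShell])
  } else {
    feat <- matrix(smooth1[idxShell], ncol = 1)
  }
  set.seed(seed)
  samp <- if (length(idxShell) > maxSample)
    sample(length(idxShell), maxSample) else seq_along(idxShell)
  if (mode == "lamellipodia") {
    gm <- mclust::Mclust(feat[samp, , drop = FALSE], G = 3,
                         verbose = FALSE)
    cls <- predict(gm, feat)$classification
    means <- tapply(feat[, 1], cls, mean)
  } else {
    km <- stats::kmeans(feat[samp, , drop = FALSE], centers = 3,
                        nstart = 5)
    ctr <- km$centers
    dmat <- outer(feat[, 1], ctr[, 1], function(a, b) (a - b)^2)
    cls <- max.col(-dmat)
    means <- ctr[, 1]
  }
  if (diff(range(means)) < 1e-6) {
    warning("no separable high-curvature class; empty instances")
    return(integer(nrow(topoMesh@vertices)))
  }
  hi <- which.max(means)
  hhigh <- array(FALSE, d)
  hhigh[idxShell[cls == hi]] <- TRUE
  cc <- array(cpp_cc3d(hhigh, d[1], d[2], d[3]), d)
  sizes <- tabulate(cc[cc > 0])
  keep <- which(sizes >= minComponentVoxels)
  if (length(keep) == 0L) return(integer(nrow(topoMesh@vertices)))
  lab <- array(match(cc, keep, nomatch = 0L), d)
  lab <- expandLabels3D(lab, 3L)
  # transfer to the mesh by nearest voxel
  P <- round(topoMesh@vertices)
  for (c in 1:3) P[, c] <- pmin(pmax(P[, c], 1), d[c])
  vlab <- lab[cbind(P[, 1], P[, 2], P[, 3])]
  vlab[binarySeg == 0L] <- 0L
  # keep labels with enough Cartesian area
  if (max(vlab) > 0) {
    aPer <- tapplySum(areas[vlab > 0], vlab[vlab > 0], max(vlab))
    good <- which(aPer > minLabelArea)
    vlab <- ifelse(vlab %in% good, vlab, 0L)
  }
  if (!any(vlab > 0)) return(integer(nrow(topoMesh@vertices)))
  vlab <- match(vlab, sort(unique(vlab))) - 1L  # contiguous, 0 = bg
  ls <- labelSpreading(A, vlab, iterations = 10L, clamp = 0.99,
                       backgroundClass = FALSE)
  out <- ls$labels
  out[binarySeg == 0L] <- 0L
  ids <- setdiff(sort(unique(out)), 0L)
  as.integer(match(out, ids, nomatch = 0L))
}

# ---- disk / square unwrapping ---------------------------------------------

# elliptical grid mapping disk -> square, vectorized
diskToSquare <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  sq <- function(v) sqrt(pmax(v, 0))
  u <- 0.5 * sq(2 + x^2 - y^2 + 2 * sqrt(2) * x) -
    0.5 * sq(2 + x^2 - y^2 - 2 * sqrt(2) * x)
  v <- 0.5 * sq(2 - x^2 + y^2 + 2 * sqrt(2) * y) -
    0.5 * sq(2 - x^2 + y^2 - 2 * sqrt(2) * y)
  unname(cbind(u, v))
}

#' Square parameterization of an open protrusion submesh
#'
#' Harmonic disk map (boundary on the unit circle by arc-length
#' fractions, interior by solving the cotangent Laplace system), followed
#' by equiareal relaxation of the interior (2D area-distortion advection
#' with fold rejection), the elliptical disk-to-square mapping, and
#' rasterization to an N x N lookup grid.
#'
#' @param submesh open genus-0 \linkS4class{SurfaceMesh} with exactly one
#'   boundary loop.
#' @param N output grid size.
#' @param relaxIterations equiareal relaxation cap (0 disables).
#' @return list: \code{vertex2D} (square coordinates in [-1,1]^2),
#'   \code{disk2D} (the relaxed disk coordinates before squaring),
#'   \code{coords} (N,N,3 lookup), \code{faceIndex}, \code{weights},
#'   \code{inside} (pixel mask), \code{faces}, \code{lambdaGlobal}.
#' @export
unwrapProtrusion <- function(submesh, N = 128L, relaxIterations = 100L) {
  top <- surfaceTopology(submesh)
  if (top@boundaryLoops != 1L || is.na(top@genus) || top@genus != 0L)
    stop("submesh must be an open genus-0 surface with one boundary loop",
         " (impute holes first)")
  loops <- boundaryLoops(submesh@faces)
  loop <- loops[[1]]
  V <- submesh@vertices; F <- submesh@faces
  n <- nrow(V)
  seg <- sqrt(rowSums((V[c(loop[-1], loop[1]), , drop = FALSE] -
                       V[loop, , drop = FALSE])^2))
  frac <- cumsum(c(0, seg[-length(seg)])) / sum(seg)
  ang <- 2 * pi * frac
  bpos <- cbind(cos(ang), sin(ang))
  ops <- buildOperators(submesh, laplacianKind = "robust")
  L <- ops$laplacian
  isB <- logical(n); isB[loop] <- TRUE
  I <- which(!isB); B <- which(isB)
  xy <- matrix(0, n, 2)
  xy[loop, ] <- bpos
  if (length(I)) {
    LII <- L[I, I, drop = FALSE]
    LIB <- L[I, B, drop = FALSE]
    xy[I, ] <- as.matrix(Matrix::solve(LII, -LIB %*% xy[B, , drop = FALSE]))
  }
  # equiareal relaxation of the interior (boundary fixed)
  a3 <- triangleAreas(V, F)
  a3n <- a3 / sum(a3)
  lambdaOf <- function(xy2) {
    V2 <- cbind(xy2, 0)
    a2 <- triangleAreas(V2, F)
    a3n / (a2 / sum(a2))
  }
  signedArea2 <- function(xy2) {
    (xy2[F[, 2], 1] - xy2[F[, 1], 1]) * (xy2[F[, 3], 2] - xy2[F[, 1], 2]) -
      (xy2[F[, 2], 2] - xy2[F[, 1], 2]) * (xy2[F[, 3], 1] - xy2[F[, 1], 1])
  }
  orient0 <- sign(sum(signedArea2(xy)))
  step <- 0.2
  for (it in seq_len(relaxIterations)) {
    lamF <- lambdaOf(xy)
    if (abs(stats::median(lamF) - 1) < 0.005 && it > 1) break
    V2 <- cbind(xy, 0)
    a2 <- triangleAreas(V2, F)
    lamV <- faceToVertex(F, n, lamF, a2)[, 1]
    G <- faceGradient(V2, F, log(pmax(lamV, 1e-12)))[, 1:2, drop = FALSE]
    Gv <- faceToVertex(F, n, -G, a2)
    nrm <- sqrt(rowSums(Gv^2))
    med <- stats::median(nrm[I])
    if (!is.finite(med) || med < 1e-14) break
    lbar <- sqrt(mean(a2) * 4 / sqrt(3))
    move <- Gv * (step * lbar / med)
    cand <- xy
    cand[I, ] <- xy[I, ] + move[I, , drop = FALSE]
    sa <- signedArea2(cand)
    if (any(sign(sa) != orient0)) { step <- step / 2
      if (step < 1e-3) break else next }
    xy <- cand
  }
  lamG <- mean(lambdaOf(xy))
  sqxy <- diskToSquare(xy)
  # rasterize to an N x N grid over [-1, 1]^2
  px <- seq(-1, 1, length.out = N)
  P <- cbind(rep(px, N), rep(px, each = N), 0)
  V2 <- cbind(sqxy, 0)
  q <- cpp_closest_triangle(V2, F, P)
  inside <- q$dist < 2.5 / N
  tri <- F[q$face, , drop = FALSE]
  coords <- q$bary[, 1] * V[tri[, 1], , drop = FALSE] +
    q$bary[, 2] * V[tri[, 2], , drop = FALSE] +
    q$bary[, 3] * V[tri[, 3], , drop = FALSE]
  list(vertex2D = sqxy, disk2D = xy, coords = array(coords, c(N, N, 3)),
       faceIndex = matrix(q$face, N, N),
       weights = array(q$bary, c(N, N, 3)),
       inside = matrix(inside, N, N), faces = F, lambdaGlobal = lamG)
}

# pull a per-vertex field through a square parameterization
pullbackSquare <- function(sq, field) {
  tri <- sq$faces[sq$faceIndex, , drop = FALSE]
  img <- sq$weights[, , 1] * field[tri[, 1]] +
    sq$weights[, , 2] * field[tri[, 2]] +
    sq$weights[, , 3] * field[tri[, 3]]
  matrix(img, nrow(sq$faceIndex), ncol(sq$faceIndex))
}

# ---- refinement of undersegmented blebs ------------------------------------

#' Split undersegmented (conjoined) blebs by gradient watershed
#'
#' Per label: small complement components are absorbed so the submesh is
#' an open genus-0 surface; the submesh is downsampled, square-unwrapped,
#' the mean curvature pulled back, thresholded at the upper 3-class Otsu
#' threshold of H over the whole mesh, morphologically closed, and split
#' by watershed on the Euclidean distance transform. Split seeds are
#' diffused over the full mesh (10 iterations, clamp 0.99), masked by the
#' binary segmentation and filtered at 10 voxel^2.
#'
#' @param mesh Cartesian \linkS4class{SurfaceMesh}.
#' @param labels per-vertex instance labels.
#' @param H per-vertex mean curvature.
#' @param A affinity matrix (recomputed if NULL).
#' @param gridN unwrap grid size.
#' @return integer per-vertex refined labels.
#' @export
refineSplitBlebs <- function(mesh, labels, H, A = NULL, gridN = 128L) {
  if (is.null(A)) A <- buildAffinity(mesh, 0.9)
  areas <- vertexAreas(mesh)
  hthr <- otsuUpperThreshold(H)
  n <- nrow(mesh@vertices)
  newLabels <- integer(n)
  nextId <- 0L
  for (l in setdiff(sort(unique(labels)), 0L)) {
    vset <- which(labels == l)
    pieces <- tryCatch({
      comp <- affinityComponents(A, !(seq_len(n) %in% vset))
      if (max(comp) > 0) {
        csize <- tabulate(comp[comp > 0])
        small <- which(csize < 0.1 * n)
        vset <- sort(c(vset, which(comp %in% small & comp > 0)))
      }
      sm <- submeshByVertices(mesh, vset)
      sub <- sm$mesh
      subTop <- surfaceTopology(sub)
      if (subTop@boundaryLoops != 1L) stop("not a disk")
      ds <- if (nrow(sub@vertices) > 200L)
        remeshUniform(sub, max(50L, nrow(sub@vertices) %/% 4L),
                      relaxIterations = 3L) else sub
      # downsampling may close or complicate the patch; keep it open
      if (surfaceTopology(ds)@boundaryLoops != 1L) ds <- sub
      sq <- unwrapProtrusion(ds, N = gridN, relaxIterations = 30L)
      Hds <- transferScalars(mesh, ds, H, method = "nearest")
      img <- pullbackSquare(sq, Hds)
      bin <- img > hthr & sq$inside
      binC <- EBImage::closing(EBImage::Image(bin * 1),
                               EBImage::makeBrush(3, "disc")) > 0.5
      edt <- matrix(cpp_edt3d(!as.matrix(binC), gridN, gridN, 1L),
                    gridN, gridN)
      # tolerance scales with the blob depth so shallow satellite maxima
      # (square corners, ragged edges) do not split a single dome, while
      # genuinely conjoined domes still separate at their waist
      ws <- EBImage::watershed(EBImage::Image(edt),
                               tolerance = max(1, 0.3 * max(edt)))
      wsm <- as.matrix(EBImage::imageData(ws))
      wsm[!as.matrix(binC)] <- 0L
      if (max(wsm) < 1L) stop("no watershed regions")
      # drop sliver basins (< 10% of the high-curvature footprint); the
      # re-diffusion reassigns their pixels to the surviving labels
      szs <- tabulate(wsm[wsm > 0L])
      wsm[wsm %in% which(szs < 0.1 * sum(wsm > 0L))] <- 0L
      if (max(wsm) < 1L) stop("no watershed regions")
      # pixel labels -> downsampled submesh vertices (nearest pixel)
      pxy <- round((sq$vertex2D + 1) * (gridN - 1) / 2 + 1)
      pxy[pxy < 1] <- 1; pxy[pxy > gridN] <- gridN
      vl <- wsm[cbind(pxy[, 1], pxy[, 2])]
      # -> original submesh vertices (nearest downsampled vertex)
      q <- cpp_closest_triangle(ds@vertices, ds@faces,
                                mesh@vertices[vset, , drop = FALSE])
      tri <- ds@faces[q$face, , drop = FALSE]
      pick <- max.col(q$bary, ties.method = "first")
      lab0 <- vl[tri[cbind(seq_len(nrow(tri)), pick)]]
      list(vset = vset, lab = lab0)
    }, error = function(e) NULL)
    if (is.null(pieces) || length(setdiff(unique(pieces$lab), 0L)) < 1L) {
      nextId <- nextId + 1L
      newLabels[labels == l] <- nextId
      next
    }
    for (piece in setdiff(sort(unique(pieces$lab)), 0L)) {
      nextId <- nextId + 1L
      newLabels[pieces$vset[pieces$lab == piece]] <- nextId
    }
  }
  if (max(newLabels) == 0L) return(newLabels)
  ls <- labelSpreading(A, newLabels, iterations = 10L, clamp = 0.99,
                       backgroundClass = FALSE)
  out <- ls$labels
  out[labels == 0L] <- 0L
  if (any(out > 0L)) {
    aPer <- tapplySum(areas[out > 0L], out[out > 0L], max(out))
    out[out %in% which(aPer < 10)] <- 0L
  }
  ids <- setdiff(sort(unique(out)), 0L)
  as.integer(match(out, ids, nomatch = 0L))
}

# ---- decomposition: inpainting, depth propagation, volumization ------------

#' Harmonic inpainting of masked pixels
#'
#' Masked pixels are solved as the discrete Laplace equation with
#' Dirichlet data from the unmasked pixels (exact sparse solve): smooth
#' imputation of removed protrusion footprints in the d_ref image.
#'
#' @param img 2D numeric image.
#' @param mask logical matrix, TRUE = to inpaint (strictly inside).
#' @return inpainted image.
#' @export
inpaintReference <- function(img, mask) {
  stopifnot(identical(dim(img), dim(mask)))
  if (all(mask)) stop("cannot inpaint a fully masked image")
  if (!any(mask)) return(img)
  nr <- nrow(img); nc <- ncol(img)
  id <- matrix(0L, nr, nc)
  unk <- which(mask)
  id[unk] <- seq_along(unk)
  m <- length(unk)
  ii <- c(); jj <- c(); xx <- c(); rhs <- numeric(m)
  rc <- arrayInd(unk, dim(img))
  for (dr in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
    r2 <- pmin(pmax(rc[, 1] + dr[1], 1L), nr)
    c2 <- pmin(pmax(rc[, 2] + dr[2], 1L), nc)
    nb <- cbind(r2, c2)
    nbId <- id[nb]
    known <- nbId == 0L
    rhs[known] <- rhs[known] + img[nb[known, , drop = FALSE]]
    ii <- c(ii, which(!known)); jj <- c(jj, nbId[!known])
    xx <- c(xx, rep(-1, sum(!known)))
  }
  Amat <- Matrix::sparseMatrix(i = c(ii, seq_len(m)), j = c(jj, seq_len(m)),
                               x = c(xx, rep(4, m)), dims = c(m, m))
  sol <- as.numeric(Matrix::solve(Amat, rhs))
  out <- img
  out[unk] <- sol
  out
}

#' Propagate surface instance labels through the topographic depth
#'
#' Surface labels are rasterized into the topographic volume (integer
#' coordinates, 3-voxel expansion, masked by the binary), then marker
#' watershed is applied slice by slice from the top (d = D) to the bottom
#' (d = 1): the seeds of a slice are the labels of the previous slice
#' (taking precedence) combined with the slice's own rasterized surface
#' labels, grown over the slice's foreground using the Euclidean distance
#' transform.
#'
#' @param topoBinary 3D logical array (d, v, u).
#' @param topoMesh topographic mesh carrying the labels.
#' @param vertexLabels integer per-vertex labels.
#' @return 3D integer array of volumetric labels.
#' @export
propagateLabelsDepth <- function(topoBinary, topoMesh, vertexLabels) {
  d <- dim(topoBinary)
  fg <- array(topoBinary > 0.5, d)
  lab <- array(0L, d)
  P <- round(topoMesh@vertices)
  for (c in 1:3) P[, c] <- pmin(pmax(P[, c], 1), d[c])
  sel <- vertexLabels > 0L
  lab[P[sel, , drop = FALSE]] <- vertexLabels[sel]
  lab <- expandLabels3D(lab, 3L)
  lab[!fg] <- 0L
  prev <- matrix(0L, d[2], d[3])
  for (k in rev(seq_len(d[1]))) {
    cur <- matrix(lab[k, , ], d[2], d[3])
    seeds <- cur
    seeds[prev > 0L] <- prev[prev > 0L]  # previous slice takes precedence
    msk <- matrix(fg[k, , ], d[2], d[3])
    seeds[!msk] <- 0L
    if (any(seeds > 0L) && any(msk)) {
      edt <- matrix(cpp_edt3d(!msk, d[2], d[3], 1L), d[2], d[3])
      grown <- EBImage::propagate(EBImage::Image(edt),
                                  EBImage::Image(seeds), mask = msk)
      cur <- as.matrix(EBImage::imageData(grown))
      storage.mode(cur) <- "integer"
    } else cur <- seeds
    lab[k, , ] <- cur
    prev <- cur
  }
  lab
}

#' Volumize individual protrusions
#'
#' Cortical (reference) voxels are masked out, each label keeps its
#' largest connected region, and per-protrusion closed meshes and
#' volumes are reported.
#'
#' @param volLabels 3D integer label array (d, v, u).
#' @param referenceBinary 3D logical array of the cortical reference
#'   volume.
#' @param space optional \linkS4class{TopographicSpace}: protrusion
#'   meshes are mapped to Cartesian coordinates and volumes are corrected
#'   by the differential volume element.
#' @param meshes also build per-protrusion meshes.
#' @return list with \code{labels} (cleaned volume), \code{table}
#'   (data.frame label/voxels/volume), \code{meshes}.
#' @export
volumizeProtrusions <- function(volLabels, referenceBinary, space = NULL,
                                meshes = FALSE) {
  d <- dim(volLabels)
  lab <- volLabels
  lab[referenceBinary > 0.5] <- 0L
  dV <- if (!is.null(space)) topographicDV(space) else NULL
  ids <- setdiff(sort(unique(as.integer(lab))), 0L)
  outMeshes <- list()
  rows <- list()
  cleaned <- array(0L, d)
  for (l in ids) {
    m <- lab == l
    cc <- array(cpp_cc3d(m, d[1], d[2], d[3]), d)
    if (max(cc) == 0L) next
    big <- which.max(tabulate(cc[cc > 0L]))
    m <- cc == big
    cleaned[m] <- l
    vox <- sum(m)
    vol <- if (!is.null(dV)) sum(dV[m]) else vox
    rows[[length(rows) + 1L]] <- data.frame(label = l, voxels = vox,
                                            volume = vol)
    if (meshes) {
      msh <- tryCatch({
        mm <- topographicMesh(m, remeshFraction = NULL)
        if (nrow(mm@vertices) > 1000L)
          mm <- remeshUniform(mm, nrow(mm@vertices) %/% 4L,
                              relaxIterations = 3L)
        if (!is.null(space)) mm <- suppressWarnings(topoToCartesian(space, mm))
        mm
      }, error = function(e) NULL)
      outMeshes[[as.character(l)]] <- msh
    }
  }
  list(labels = cleaned,
       table = if (length(rows)) do.call(rbind, rows) else
         data.frame(label = integer(0), voxels = integer(0),
                    volume = numeric(0)),
       meshes = outMeshes)
}
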