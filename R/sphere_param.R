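# Quasi-conformal spherical parameterization of genus-0 surfaces and
# advection-based equiareal relaxation with selectable stopping criteria.

#' Count flipped spherical faces
#'
#' Number of faces whose orientation disagrees with the outward sphere
#' normal (nonpositive signed triple product of the corner positions);
#' 0 for a fold-free spherical parameterization.
#'
#' @param V unit-sphere vertex matrix.
#' @param F face matrix.
#' @return integer count.
#' @export
countFlippedSphereFaces <- function(V, F) {
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  cc <- V[F[, 3], , drop = FALSE]
  s <- a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
       a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
       a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
  sum(s <= 0)
}

#' Quasi-conformal map of a genus-0 surface to the unit sphere
#'
#' Runs conformalized mean curvature flow to its spherical limit: cMCF
#' with the Laplacian frozen at iteration 0 preserves the conformal class
#' while the shape flows to a round sphere. Iterations stop when the
#' vertex radii are uniform to \code{sphericityTol}; vertices are then
#' centered and projected onto the unit sphere.
#'
#' @param ref closed genus-0 \linkS4class{SurfaceMesh}.
#' @param dt flow time step (on the mesh rescaled to unit area).
#' @param maxIterations iteration cap.
#' @param sphericityTol relative radius spread at which to stop.
#' @return a \linkS4class{SphereParam} (status \code{"conformal"}).
#' @export
sphericalParameterize <- function(ref, dt = 0.01, maxIterations = 400L,
                                  sphericityTol = 2e-4) {
  top <- surfaceTopology(ref)
  if (is.na(top@genus) || top@genus != 0L || !top@watertight)
    stop("spherical parameterization requires a watertight genus-0 mesh; ",
         "got genus ", top@genus)
  # work at unit scale so dt is shape-independent
  V <- sweep(ref@vertices, 2, colMeans(ref@vertices))
  V <- V / sqrt(surfaceArea(SurfaceMesh(V, ref@faces,
                                        dropDegenerate = FALSE)))
  cur <- SurfaceMesh(V, ref@faces, representation = "sphere",
                     dropDegenerate = FALSE)
  ops0 <- buildOperators(cur, laplacianKind = "robust")
  L0 <- ops0$laplacian
  for (t in seq_len(maxIterations)) {
    ops <- buildOperators(cur, laplacianKind = "robust",
                          onDegenerate = "robust")
    A <- ops$mass - dt * L0
    Vn <- as.matrix(Matrix::solve(A, ops$mass %*% cur@vertices))
    if (!all(is.finite(Vn))) stop("conformal flow broke down at iteration ", t)
    Vn <- sweep(Vn, 2, colMeans(Vn))
    r <- sqrt(rowSums(Vn^2))
    Vn <- Vn / mean(r)
    cur@vertices <- Vn
    spread <- stats::sd(r) / mean(r)
    if (spread < sphericityTol) break
  }
  # center and project to the exact unit sphere
  Vs <- cur@vertices
  for (it in 1:50) {
    Vs <- Vs / sqrt(rowSums(Vs^2))
    a <- triangleAreas(Vs, ref@faces)
    w <- numeric(nrow(Vs))
    for (c in 1:3) w <- w + tapplySum(a / 3, ref@faces[, c], nrow(Vs))
    cen <- colSums(Vs * w) / sum(w)
    if (sqrt(sum(cen^2)) < 1e-9) break
    Vs <- sweep(Vs, 2, cen)
  }
  Vs <- Vs / sqrt(rowSums(Vs^2))
  nflip <- countFlippedSphereFaces(Vs, ref@faces)
  if (nflip > 0)
    stop("spherical parameterization has ", nflip, " flipped face(s)")
  sphere <- SurfaceMesh(Vs, ref@faces, representation = "sphere",
                        dropDegenerate = FALSE)
  rep0 <- faceDistortion(ref, sphere)
  hist0 <- data.frame(iteration = 0L,
                      medianLambda = rep0@medianLambda,
                      iqrLambda = stats::IQR(rep0@lambda),
                      globalQ = rep0@globalQ,
                      mips = rep0@criteria[["mips"]],
                      areaMips = rep0@criteria[["area_mips"]],
                      isometric = rep0@criteria[["isometric"]],
                      nFlipped = nflip)
  new("SphereParam", sphere = sphere, reference = ref, history = hist0,
      stopIteration = 0L, status = "conformal")
}

# Per-face gradient of a per-vertex scalar on a triangle mesh:
# grad f = sum_i f_i (N x e_i) / (2A), e_i the edge opposite corner i.
faceGradient <- function(V, F, f) {
  e1 <- V[F[, 3], , drop = FALSE] - V[F[, 2], , drop = FALSE]  # opp corner 1
  e2 <- V[F[, 1], , drop = FALSE] - V[F[, 3], , drop = FALSE]
  e3 <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  Nr <- faceNormalsRaw(V, F)
  A2 <- sqrt(rowSums(Nr^2))
  A2[A2 == 0] <- 1e-300
  Nu <- Nr / A2
  crossm <- function(n, e) cbind(n[, 2] * e[, 3] - n[, 3] * e[, 2],
                                 n[, 3] * e[, 1] - n[, 1] * e[, 3],
                                 n[, 1] * e[, 2] - n[, 2] * e[, 1])
  (f[F[, 1]] * crossm(Nu, e1) + f[F[, 2]] * crossm(Nu, e2) +
     f[F[, 3]] * crossm(Nu, e3)) / A2
}

# Area-weighted average of a per-face quantity onto vertices.
faceToVertex <- function(F, nV, x, areas) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  out <- matrix(0, nV, ncol(x))
  wsum <- numeric(nV)
  for (c in 1:3) {
    wsum <- wsum + tapplySum(areas, F[, c], nV)
    for (d in seq_len(ncol(x)))
      out[, d] <- out[, d] + tapplySum(areas * x[, d], F[, c], nV)
  }
  out / pmax(wsum, 1e-300)
}

#' Relax area distortion of a spherical parameterization
#'
#' Iterative advection scheme: per iteration the per-face area-distortion
#' factor \code{lambda = a_ref/a_sphere} (normalized areas) is computed,
#' the advection field \code{V = -grad(log lambda)} is evaluated with the
#' per-face gradient operator, normalized by its median norm times the
#' mean edge length, averaged onto vertices, projected onto the tangent
#' plane, applied through one active-contour cMCF step of stiffness
#' \code{delta} and step size \code{epsilon}, and the vertices are
#' re-projected onto the unit sphere. Stops at the chosen criterion, on
#' triangle collapse (minimum interior angle below 0.5 degrees, a flipped
#' face, or non-finite vertices), or at \code{maxIterations}. On collapse
#' with \code{retryDelta} set, the relaxation restarts once with the
#' slower stiffness.
#'
#' @param sp a \linkS4class{SphereParam}.
#' @param epsilon advection step size.
#' @param delta cMCF stiffness.
#' @param maxIterations iteration cap.
#' @param criterion \code{"equiareal"} (default), \code{"conformal_mips"},
#'   \code{"isometric_sum"} or \code{"area_mips"}; the loop always runs to
#'   equiareal convergence or collapse, and the reported stop index is the
#'   criterion's optimum over the recorded history.
#' @param theta isometric-criterion weight.
#' @param tol equiareal tolerance on |median lambda - 1|.
#' @param retryDelta stiffness for one retry after collapse (NULL: none).
#' @return a \linkS4class{SphereParam} with updated sphere, history,
#'   \code{stopIteration} and status.
#' @export
relaxAreaDistortion <- function(sp, epsilon = 1, delta = 0.1,
                                maxIterations = 100L,
                                criterion = "equiareal", theta = 0.5,
                                tol = 0.01, retryDelta = 5e-3) {
  ref <- sp@reference
  F <- sp@sphere@faces
  nV <- nrow(sp@sphere@vertices)
  aref <- triangleAreas(ref@vertices, F)
  arefN <- aref / sum(aref)
  runOnce <- function(delta) {
    Vs <- sp@sphere@vertices
    hist <- sp@history[1, , drop = FALSE]
    snaps <- list(`0` = Vs)
    status <- "relaxed"
    for (t in seq_len(maxIterations)) {
      asph <- triangleAreas(Vs, F)
      lamF <- arefN / (asph / sum(asph))
      lamV <- faceToVertex(F, nV, lamF, asph)[, 1]
      G <- faceGradient(Vs, F, log(pmax(lamV, 1e-12)))
      Vf <- -G
      nrm <- sqrt(rowSums(Vf^2))
      med <- stats::median(nrm)
      if (med < 1e-14) med <- 1e-14
      sphereMesh <- SurfaceMesh(Vs, F, representation = "sphere",
                                dropDegenerate = FALSE)
      lbar <- meanEdgeLength(sphereMesh)
      Vf <- Vf * (lbar / med)
      Vv <- faceToVertex(F, nV, Vf, asph)
      Nv <- vertexNormals(sphereMesh)
      Vt <- Vv - rowSums(Vv * Nv) * Nv
      stepped <- activeContourStep(sphereMesh, epsilon * Vt, delta)
      Vn <- stepped@vertices
      Vn <- sweep(Vn, 2, colMeans(Vn))
      Vn <- Vn / sqrt(rowSums(Vn^2))
      # collapse / fold checks
      ang <- interiorAngles(Vn, F)
      bad <- !all(is.finite(Vn)) || min(ang) < 0.5 * pi / 180 ||
        countFlippedSphereFaces(Vn, F) > 0
      if (bad) { status <- "collapsed"; break }
      Vs <- Vn
      snaps[[as.character(t)]] <- Vs
      repT <- faceDistortion(ref, SurfaceMesh(Vs, F, dropDegenerate = FALSE),
                             theta = theta)
      hist <- rbind(hist, data.frame(
        iteration = t, medianLambda = repT@medianLambda,
        iqrLambda = stats::IQR(repT@lambda), globalQ = repT@globalQ,
        mips = repT@criteria[["mips"]],
        areaMips = repT@criteria[["area_mips"]],
        isometric = repT@criteria[["isometric"]],
        nFlipped = countFlippedSphereFaces(Vs, F)))
      if (abs(repT@medianLambda - 1) < tol) break
    }
    list(hist = hist, snaps = snaps, status = status)
  }
  res <- runOnce(delta)
  if (res$status == "collapsed" && !is.null(retryDelta) &&
      retryDelta < delta)
    res <- runOnce(retryDelta)
  stopIt <- evaluateStopCriterion(res$hist, criterion, theta = theta,
                                  tol = tol)
  Vstop <- res$snaps[[as.character(stopIt)]]
  out <- sp
  out@sphere <- SurfaceMesh(Vstop, F, representation = "sphere",
                            dropDegenerate = FALSE)
  out@history <- res$hist
  out@stopIteration <- as.integer(stopIt)
  out@status <- res$status
  out
}

#' Pick the stopping iteration for a relaxation history
#'
#' \code{"equiareal"}: first iteration with |median lambda - 1| below
#' \code{tol} (last iteration if never reached). \code{"conformal_mips"}:
#' iteration 0 (the conformal start minimizes MIPS by construction).
#' \code{"isometric_sum"}: argmin of the combined conformal +
#' log-area-distortion criterion. \code{"area_mips"}: argmin of the
#' area-preserving MIPS aggregate.
#'
#' @param history data.frame as produced by
#'   \code{\link{relaxAreaDistortion}} (or a SphereParam).
#' @param criterion criterion name.
#' @param theta isometric weight (recorded at history time).
#' @param tol equiareal tolerance.
#' @return integer iteration.
#' @export
evaluateStopCriterion <- function(history,
                                  criterion = c("equiareal",
                                                "conformal_mips",
                                                "isometric_sum",
                                                "area_mips"),
                                  theta = 0.5, tol = 0.01) {
  criterion <- match.arg(criterion)
  if (is(history, "SphereParam")) history <- history@history
  if (nrow(history) == 0L) stop("empty history")
  switch(criterion,
    equiareal = {
      hit <- which(abs(history$medianLambda - 1) < tol)
      if (length(hit)) history$iteration[hit[1]]
      else history$iteration[nrow(history)]
    },
    conformal_mips = 0L,
    isometric_sum = history$iteration[which.min(history$isometric)],
    area_mips = history$iteration[which.min(history$areaMips)])
}
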