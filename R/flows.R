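# Conformalized mean curvature flow (cMCF), its automatic stopping rule,
# the active-contour displacement step, and cMCF flattening of open
# topographic surfaces.

#' Flow configuration
#'
#' @param dt implicit time step (> 0).
#' @param maxIterations maximum number of iterations T.
#' @param deltaThresh stopping threshold on the change of mean absolute
#'   Gaussian curvature.
#' @param tMin minimum iteration before stopping is allowed.
#' @param laplacianKind \code{"cotangent"} or \code{"robust"}.
#' @param normalize area-normalize and recenter after every iteration.
#' @return list of class \code{"FlowConfig"}.
#' @export
flowConfig <- function(dt = 5e-4, maxIterations = 50L, deltaThresh = 1e-5,
                       tMin = 1L, laplacianKind = "robust",
                       normalize = TRUE) {
  stopifnot(dt >= 0, maxIterations >= 1, tMin <= maxIterations)
  structure(list(dt = dt, maxIterations = as.integer(maxIterations),
                 deltaThresh = deltaThresh, tMin = as.integer(tMin),
                 laplacianKind = laplacianKind, normalize = normalize),
            class = "FlowConfig")
}

# Mean absolute discrete Gaussian curvature (area-normalized deficits).
# Computed inline so the flow also runs on meshes with small holes,
# where the exported angle-deficit operator refuses boundaries.
meanAbsGaussianCurvature <- function(mesh) {
  V <- mesh@vertices; F <- mesh@faces
  ang <- interiorAngles(V, F)
  n <- nrow(V)
  tot <- numeric(n)
  for (c in 1:3) tot <- tot + tapplySum(ang[, c], F[, c], n)
  a <- triangleAreas(V, F)
  va <- numeric(n)
  for (c in 1:3) va <- va + tapplySum(a / 3, F[, c], n)
  mean(abs((2 * pi - tot) / pmax(va, 1e-12)))
}

#' Run conformalized mean curvature flow
#'
#' Solves \code{(M_t - dt * L0) v(t+1) = M_t v(t)} per iteration with the
#' Laplacian frozen at iteration 0 (this is what conformalizes the flow),
#' then rescales to the input surface area and recenters at the origin.
#' The mean absolute Gaussian curvature is recorded per iteration for the
#' automatic stopping rule.
#'
#' @param mesh closed \linkS4class{SurfaceMesh}.
#' @param cfg a \code{\link{flowConfig}}.
#' @param recordEvery keep a vertex snapshot every this many iterations
#'   (1 keeps all; snapshots at iteration 0 and the last are always kept).
#' @param conformalized freeze the Laplacian at iteration 0 (TRUE, cMCF)
#'   or rebuild it each iteration (plain MCF; test instrumentation).
#' @param stopEarly terminate once the elbow stopping rule has triggered
#'   (at or after \code{tMin}); the full trace to \code{maxIterations} is
#'   recorded otherwise.
#' @return list of class \code{"FlowHistory"}: \code{snapshots} (named by
#'   iteration), \code{Kbar}, \code{faces}, \code{status}.
#' @export
runCMCF <- function(mesh, cfg = flowConfig(), recordEvery = 1L,
                    conformalized = TRUE, stopEarly = FALSE) {
  # evolve at unit surface area so dt is scale-independent; snapshots are
  # mapped back into the input (voxel) frame
  cen0 <- colMeans(mesh@vertices)
  scale0 <- sqrt(surfaceArea(mesh))
  toVoxel <- function(V) sweep(V * scale0, 2, cen0, `+`)
  cur <- mesh
  cur@vertices <- sweep(mesh@vertices, 2, cen0) / scale0
  ops <- buildOperators(cur, laplacianKind = cfg$laplacianKind,
                        onDegenerate = "robust")
  L0 <- ops$laplacian
  snaps <- list("0" = mesh@vertices)
  Kbar <- meanAbsGaussianCurvature(cur)
  status <- "ok"
  for (t in seq_len(cfg$maxIterations)) {
    opsT <- buildOperators(cur, laplacianKind = cfg$laplacianKind,
                           onDegenerate = "robust")
    L <- if (conformalized) L0 else opsT$laplacian
    A <- opsT$mass - cfg$dt * L
    Vn <- tryCatch(as.matrix(Matrix::solve(A, opsT$mass %*% cur@vertices)),
                   error = function(e) NULL)
    if (is.null(Vn) || !all(is.finite(Vn))) { status <- "singular"; break }
    cur@vertices <- Vn
    if (cfg$normalize) {
      a <- surfaceArea(cur)
      cur@vertices <- cur@vertices / sqrt(a)
      cur@vertices <- sweep(cur@vertices, 2, colMeans(cur@vertices))
    }
    Kbar <- c(Kbar, meanAbsGaussianCurvature(cur))
    if (t %% recordEvery == 0L || t == cfg$maxIterations)
      snaps[[as.character(t)]] <- toVoxel(cur@vertices)
    if (stopEarly && t >= cfg$tMin && t >= 2L) {
      dK <- diff(Kbar)
      if (abs(dK[t]) < cfg$deltaThresh || dK[t] > 0) break
    }
  }
  structure(list(snapshots = snaps, Kbar = Kbar, faces = mesh@faces,
                 representation = mesh@representation, status = status,
                 config = cfg),
            class = "FlowHistory")
}

#' Automatic stopping iteration of a curvature flow
#'
#' The elbow of the mean absolute Gaussian curvature trace: the first
#' iteration t at which the per-iteration change
#' \code{dK(t) = Kbar(t) - Kbar(t-1)} either shrinks below the threshold
#' in magnitude or turns positive (curvature stops decreasing). The
#' strict literal mode instead triggers on \code{dK(t) > deltaThresh}.
#' Returns \code{max(tMin, tK)}; if never triggered, the last iteration.
#'
#' @param history a \code{"FlowHistory"} (or numeric Kbar trace).
#' @param deltaThresh threshold.
#' @param tMin minimum iteration.
#' @param mode \code{"elbow"} (default) or \code{"literal"}.
#' @return integer stop iteration.
#' @export
autoStopIndex <- function(history, deltaThresh = 1e-5, tMin = 1L,
                          mode = c("elbow", "literal")) {
  mode <- match.arg(mode)
  Kbar <- if (is.list(history)) history$Kbar else history
  if (length(Kbar) < 2L) stop("history needs at least 2 iterations")
  dK <- diff(Kbar)
  trig <- if (mode == "elbow") abs(dK) < deltaThresh | dK > 0
          else dK > deltaThresh
  tK <- if (any(trig)) which(trig)[1] else length(dK)
  max(as.integer(tMin), as.integer(tK))
}

#' Mesh snapshot at a flow iteration
#' @param history FlowHistory.
#' @param iteration iteration number (must have been recorded).
#' @return \linkS4class{SurfaceMesh}.
#' @export
flowSnapshot <- function(history, iteration) {
  key <- as.character(iteration)
  if (!key %in% names(history$snapshots)) {
    have <- as.integer(names(history$snapshots))
    key <- as.character(have[which.min(abs(have - iteration))])
  }
  SurfaceMesh(history$snapshots[[key]], history$faces,
              representation = history$representation,
              dropDegenerate = FALSE)
}

#' One active-contour cMCF displacement step
#'
#' Solves \code{(M - dt*L) v+ = M (v + force)}: an implicit Laplacian
#' smoothing of the forced displacement. With
#' \code{force = alpha * grad(Phi)/|grad(Phi)|} this moves the surface
#' normally outwards (alpha > 0) or inwards (alpha < 0).
#'
#' @param mesh \linkS4class{SurfaceMesh}.
#' @param force nVertices x 3 displacement matrix.
#' @param dt stiffness (time step).
#' @param ops optional precomputed operators (\code{\link{buildOperators}});
#'   the Laplacian is taken from here, so passing the iteration-0
#'   operators gives conformalized stepping.
#' @return displaced \linkS4class{SurfaceMesh}.
#' @export
activeContourStep <- function(mesh, force, dt, ops = NULL) {
  stopifnot(nrow(force) == nrow(mesh@vertices))
  if (is.null(ops))
    ops <- buildOperators(mesh, laplacianKind = "robust")
  A <- ops$mass - dt * ops$laplacian
  rhs <- ops$mass %*% (mesh@vertices + force)
  Vn <- as.matrix(Matrix::solve(A, rhs))
  if (!all(is.finite(Vn))) stop("singular active-contour system")
  out <- mesh
  out@vertices <- Vn
  out
}

#' cMCF flattening of an open topographic surface
#'
#' Interior vertices follow standard cMCF; boundary vertices use 1D line
#' mass/Laplacian operators along the single boundary loop with the u,v
#' flux cancelled, so they move only in the depth coordinate (column 1).
#' With a large stiffness (e.g. 5e4) the surface converges toward the
#' planar (u,v) rectangle within ~50 iterations.
#'
#' @param topoMesh open \linkS4class{SurfaceMesh} (tag "topographic",
#'   columns d, v, u) with exactly one boundary loop.
#' @param iterations number of implicit steps.
#' @param delta stiffness.
#' @return flattened \linkS4class{SurfaceMesh} with the same faces.
#' @export
topographicCMCF <- function(topoMesh, iterations = 50L, delta = 5e4) {
  loops <- boundaryLoops(topoMesh@faces)
  if (length(loops) != 1L)
    stop("topographic cMCF expects exactly one boundary loop, found ",
         length(loops))
  loop <- loops[[1]]
  n <- nrow(topoMesh@vertices)
  bnd <- logical(n); bnd[loop] <- TRUE
  ops0 <- buildOperators(topoMesh, laplacianKind = "robust")
  L0 <- ops0$laplacian
  cur <- topoMesh
  nl <- length(loop)
  nxt <- c(loop[-1], loop[1])
  prv <- c(loop[nl], loop[-nl])
  for (t in seq_len(iterations)) {
    V <- cur@vertices
    ops <- buildOperators(cur, laplacianKind = "robust")
    M <- ops$mass
    # line operators along the loop
    lenN <- sqrt(rowSums((V[nxt, , drop = FALSE] - V[loop, , drop = FALSE])^2))
    lenP <- sqrt(rowSums((V[prv, , drop = FALSE] - V[loop, , drop = FALSE])^2))
    wN <- 1 / pmax(lenN, 1e-9); wP <- 1 / pmax(lenP, 1e-9)
    Lb <- Matrix::sparseMatrix(
      i = c(loop, loop, loop), j = c(nxt, prv, loop),
      x = c(wN, wP, -(wN + wP)), dims = c(n, n))
    mb <- (lenN + lenP) / 2
    # assemble: interior rows from the mesh system, boundary rows from
    # the line system
    keepI <- Matrix::Diagonal(n, as.numeric(!bnd))
    keepB <- Matrix::Diagonal(n, as.numeric(bnd))
    Mb <- Matrix::Diagonal(n, ifelse(bnd, mb, 0))
    A <- keepI %*% (M - delta * L0) + (Mb - delta * keepB %*% Lb)
    rhs <- as.matrix(keepI %*% (M %*% V) + Mb %*% V)
    # cancel the u,v flux on the boundary: for columns 2..3 add back the
    # -delta*Lb*v term so boundary u,v solve to their current values
    flux <- as.matrix(-delta * (keepB %*% (Lb %*% V)))
    rhs[, 2:3] <- rhs[, 2:3] + flux[, 2:3]
    Vn <- as.matrix(Matrix::solve(A, rhs))
    if (!all(is.finite(Vn))) stop("singular topographic cMCF system")
    cur@vertices <- Vn
  }
  cur
}
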