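# FEM operators on triangle meshes: barycentric mass and cotangent
# Laplacian, with an intrinsically mollified "robust" variant.

#' Mass and Laplacian operators of a triangle mesh
#'
#' Assembles the (lumped, barycentric) mass matrix and the cotangent
#' Laplacian used by the curvature flows. The \code{"robust"} kind applies
#' intrinsic mollification: all edge lengths are lengthened by
#' \code{1e-5 * mean(edge length)} before the cotangents are computed,
#' which bounds the weights on near-degenerate faces.
#'
#' Sign convention: off-diagonal entries are the (positive) cotangent
#' weights and the diagonal their negated row sums, so rows sum to zero
#' and the quadratic form \code{t(v) L v} is nonpositive.
#'
#' @param mesh a \linkS4class{SurfaceMesh} with at least 4 vertices.
#' @param laplacianKind \code{"cotangent"} or \code{"robust"}.
#' @param onDegenerate for the cotangent kind, \code{"error"} (default) or
#'   \code{"robust"} to silently switch when zero-area faces are present.
#' @return list with sparse matrices \code{mass} (diagonal) and
#'   \code{laplacian}.
#' @export
buildOperators <- function(mesh, laplacianKind = c("cotangent", "robust"),
                           onDegenerate = c("error", "robust")) {
  laplacianKind <- match.arg(laplacianKind)
  onDegenerate <- match.arg(onDegenerate)
  V <- mesh@vertices; F <- mesh@faces
  if (nrow(V) < 3L) stop("mesh must have at least 3 vertices")
  n <- nrow(V)
  a <- sqrt(rowSums((V[F[, 2], , drop = FALSE] - V[F[, 3], , drop = FALSE])^2))
  b <- sqrt(rowSums((V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE])^2))
  cc <- sqrt(rowSums((V[F[, 1], , drop = FALSE] - V[F[, 2], , drop = FALSE])^2))
  s <- (a + b + cc) / 2
  area2 <- s * (s - a) * (s - b) * (s - cc)
  if (laplacianKind == "cotangent" && any(area2 <= 0)) {
    if (onDegenerate == "error")
      stop("degenerate (zero-area) face(s); use laplacianKind = 'robust'")
    laplacianKind <- "robust"
  }
  if (laplacianKind == "robust") {
    eps <- 1e-5 * mean(c(a, b, cc))
    a <- a + eps; b <- b + eps; cc <- cc + eps
    s <- (a + b + cc) / 2
    area2 <- pmax(s * (s - a) * (s - b) * (s - cc), 1e-300)
  }
  area <- sqrt(pmax(area2, 0))
  # cot of angle at corner i (opposite edge a), from the law of cosines
  cotA <- (b^2 + cc^2 - a^2) / (4 * area)
  cotB <- (a^2 + cc^2 - b^2) / (4 * area)
  cotC <- (a^2 + b^2 - cc^2) / (4 * area)
  ii <- c(F[, 2], F[, 3], F[, 1])
  jj <- c(F[, 3], F[, 1], F[, 2])
  ww <- 0.5 * c(cotA, cotB, cotC)
  L <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = c(ww, ww),
                            dims = c(n, n))
  L <- L - Matrix::Diagonal(n, Matrix::rowSums(L))
  areaTrue <- triangleAreas(V, F)
  mdiag <- numeric(n)
  for (c in 1:3) mdiag <- mdiag + tapplySum(areaTrue / 3, F[, c], n)
  list(mass = Matrix::Diagonal(n, mdiag), laplacian = L)
}
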