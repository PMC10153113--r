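# Seeded generators of ground-truth test shapes: spheres carrying planted
# bleb- (hemispherical bump), lamellipodium- (ridge) and filopodium-like
# (thin tall spike) protrusions, with matched binary/intensity volumes.

#' Icosphere mesh
#'
#' @param subdivisions midpoint subdivision rounds of the icosahedron.
#' @param radius sphere radius.
#' @param center 3-vector center.
#' @return \linkS4class{SurfaceMesh} with outward-oriented faces.
#' @export
icosphere <- function(subdivisions = 3L, radius = 1, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  F <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  m <- SurfaceMesh(V / sqrt(1 + phi^2), F)
  if (subdivisions > 0L) {
    m <- subdivideMidpoint(m, subdivisions)
    m@vertices <- m@vertices / sqrt(rowSums(m@vertices^2))
  }
  m@vertices <- sweep(m@vertices * radius, 2, center, `+`)
  m
}

#' Fixture specification
#'
#' @param baseRadius sphere radius in voxels (>= 16).
#' @param motif one of \code{"bleb"} (hemispherical cap), \code{"gauss"}
#'   (smooth Gaussian bump), \code{"ridge"}, \code{"spike"},
#'   \code{"mixed"}.
#' @param k number of planted protrusions.
#' @param amplitude protrusion amplitude in units of baseRadius.
#' @param width angular width (radians).
#' @param seed RNG seed; recorded in all outputs.
#' @param subdivisions icosphere subdivision level.
#' @return list of class \code{"FixtureSpec"}.
#' @export
fixtureSpec <- function(baseRadius = 32, motif = "bleb", k = 12L,
                        amplitude = 0.2, width = 0.15, seed = 1L,
                        subdivisions = 4L, widthRange = NULL) {
  stopifnot(baseRadius >= 16, k >= 0,
            motif %in% c("bleb", "gauss", "ridge", "spike", "mixed"))
  structure(list(baseRadius = baseRadius, motif = motif, k = as.integer(k),
                 amplitude = amplitude, width = width, seed = as.integer(seed),
                 subdivisions = as.integer(subdivisions),
                 widthRange = widthRange),
            class = "FixtureSpec")
}

# Angular displacement profile of one planted motif, evaluated at unit
# directions P (n x 3). Returns per-vertex displacement in voxels.
motifDisplacement <- function(P, motif, centerDir, amp, width, tangent) {
  ct <- pmin(1, pmax(-1, P %*% centerDir))
  theta <- acos(ct)
  if (motif == "bleb") {
    # hemispherical cap: compact support with a sharp rim (bleb neck)
    amp * sqrt(pmax(0, 1 - (theta / width)^2))
  } else if (motif == "gauss") {
    amp * exp(-theta^2 / (2 * width^2))
  } else if (motif == "spike") {
    # narrower, taller, flat-topped profile (super-Gaussian)
    amp * exp(-(theta / width)^4)
  } else {  # ridge: elongated along the tangent direction
    b <- c(centerDir[2] * tangent[3] - centerDir[3] * tangent[2],
           centerDir[3] * tangent[1] - centerDir[1] * tangent[3],
           centerDir[1] * tangent[2] - centerDir[2] * tangent[1])
    along <- atan2(P %*% tangent, ct)
    perp <- asin(pmin(1, pmax(-1, P %*% b)))
    halfLen <- 3 * width
    over <- pmax(0, abs(along) - halfLen)
    amp * exp(-perp^2 / (2 * width^2)) * exp(-over^2 / (2 * width^2))
  }
}

#' Generate a seeded ground-truth fixture
#'
#' An icosphere of radius \code{baseRadius} is displaced radially by
#' \code{k} planted motifs at rejection-sampled, non-overlapping centers.
#' Per-vertex truth labels mark vertices whose displacement exceeds 50% of
#' the owning motif's amplitude. A matched binary volume (via
#' \code{\link{voxelize}}) and a cortical-shell intensity volume are
#' returned on request.
#'
#' @param spec a \code{\link{fixtureSpec}}.
#' @param volumes also build binary + intensity volumes (slower).
#' @return list with \code{mesh} (scalar field \code{"truth"} attached),
#'   \code{truth}, \code{centers}, and optionally \code{binary},
#'   \code{intensity}; plus \code{seed}.
#' @export
makeFixture <- function(spec, volumes = FALSE) {
  stopifnot(inherits(spec, "FixtureSpec"))
  set.seed(spec$seed)
  m <- icosphere(spec$subdivisions, radius = 1)
  P <- m@vertices
  k <- spec$k
  motifs <- if (spec$motif == "mixed") {
    rep(c("bleb", "ridge", "spike"), length.out = k)
  } else rep(spec$motif, k)
  widths <- if (!is.null(spec$widthRange))
    stats::runif(k, spec$widthRange[1], spec$widthRange[2])
  else rep(spec$width, max(k, 1))
  minSep <- max(2.5 * max(widths, spec$width), 0.4)
  centers <- matrix(0, 0, 3)
  tries <- 0L
  while (nrow(centers) < k) {
    cand <- stats::rnorm(3)
    cand <- cand / sqrt(sum(cand^2))
    ok <- nrow(centers) == 0L ||
      all(acos(pmin(1, pmax(-1, centers %*% cand))) > minSep)
    if (ok) centers <- rbind(centers, cand)
    tries <- tries + 1L
    if (tries > 10000L)
      stop("could not place ", k, " non-overlapping motifs")
  }
  disp <- matrix(0, nrow(P), max(k, 1))
  amps <- numeric(max(k, 1))
  for (i in seq_len(k)) {
    tang <- stats::rnorm(3)
    tang <- tang - sum(tang * centers[i, ]) * centers[i, ]
    tang <- tang / sqrt(sum(tang^2))
    ampV <- spec$amplitude * spec$baseRadius *
      (if (motifs[i] == "spike") 1.5 else 1)
    widthV <- widths[i] * (if (motifs[i] == "spike") 0.5 else 1)
    amps[i] <- ampV
    disp[, i] <- motifDisplacement(P, motifs[i], centers[i, ], ampV, widthV,
                                   tang)
  }
  total <- if (k > 0) rowSums(disp) else numeric(nrow(P))
  r <- spec$baseRadius + total
  Vout <- P * r
  truth <- integer(nrow(P))
  if (k > 0) {
    frac <- sweep(disp, 2, amps, `/`)
    best <- max.col(frac, ties.method = "first")
    hit <- frac[cbind(seq_len(nrow(P)), best)] > 0.5
    truth[hit] <- best[hit]
  }
  ctr <- rep(2 * (spec$baseRadius + max(amps, 0) + 8), 3)
  Vout <- sweep(Vout, 2, ctr, `+`)
  mesh <- SurfaceMesh(Vout, m@faces,
                      scalars = list(truth = as.numeric(truth)))
  out <- list(mesh = mesh, truth = truth,
              centers = centers, motifs = motifs, widths = widths,
              amplitudes = amps, seed = spec$seed, spec = spec)
  if (volumes) {
    bin <- voxelize(mesh, dilationRadius = 1)
    d <- dim(bin@data)
    distFg <- array(cpp_edt3d(bin@data, d[1], d[2], d[3]), d)
    distBg <- array(cpp_edt3d(!bin@data, d[1], d[2], d[3]), d)
    shell <- (bin@data & distBg <= 2) | (!bin@data & distFg <= 2)
    out$binary <- bin
    out$intensity <- array(as.numeric(shell), d)
  }
  out
}

#' Punch topological defects into a mesh
#'
#' Removes \code{nHoles} random faces (each leaving a triangular boundary
#' loop) and glues \code{nHandles} triangular-prism tubes between pairs of
#' removed, well-separated faces (each raising the genus by one).
#'
#' @param mesh closed \linkS4class{SurfaceMesh}.
#' @param nHoles number of holes.
#' @param nHandles number of handles.
#' @param seed RNG seed.
#' @return defected \linkS4class{SurfaceMesh}.
#' @export
punchDefects <- function(mesh, nHoles = 0L, nHandles = 0L, seed = 1L) {
  set.seed(seed)
  V <- mesh@vertices
  F <- mesh@faces
  need <- nHoles + 2L * nHandles
  if (need == 0L) return(mesh)
  cent <- (V[F[, 1], , drop = FALSE] + V[F[, 2], , drop = FALSE] +
           V[F[, 3], , drop = FALSE]) / 3
  chosen <- integer(0)
  cand <- sample(nrow(F))
  for (f in cand) {
    if (length(chosen) == need) break
    if (length(chosen) == 0L ||
        min(sqrt(rowSums(sweep(cent[chosen, , drop = FALSE], 2,
                               cent[f, ])^2))) > 4 * meanEdgeLength(mesh))
      chosen <- c(chosen, f)
  }
  if (length(chosen) < need) stop("mesh too small for requested defects")
  tubes <- NULL
  for (h in seq_len(nHandles)) {
    f1 <- chosen[nHoles + 2L * h - 1L]
    f2 <- chosen[nHoles + 2L * h]
    a <- F[f1, ]; b <- rev(F[f2, ])  # opposite winding for the far ring
    tubes <- rbind(tubes,
                   c(a[1], a[2], b[1]), c(a[2], b[2], b[1]),
                   c(a[2], a[3], b[2]), c(a[3], b[3], b[2]),
                   c(a[3], a[1], b[3]), c(a[1], b[1], b[3]))
  }
  F2 <- F[-chosen, , drop = FALSE]
  if (!is.null(tubes)) {
    storage.mode(tubes) <- "integer"
    F2 <- rbind(F2, tubes)
  }
  SurfaceMesh(V, F2, representation = mesh@representation,
              scalars = mesh@scalars, dropDegenerate = FALSE)
}
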