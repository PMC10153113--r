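# End-to-end orchestration of the six mapping steps and the segmentation
# stages, plus the machine-readable metrics report.

#' Pipeline configuration
#'
#' Defaults follow the per-step settings used for the morphology
#' validation runs: cMCF at most 50 iterations with dt = 5e-4; dilation
#' ball 5 for the reference voxelization; remeshing to 90% of the
#' isosurface vertex count for the reference and 50% for the topographic
#' mesh; relaxation epsilon 1, delta 0.1 with retry 5e-3; alpha = 0.5,
#' Din = 40. The cMCF stop threshold applies to the mean absolute
#' Gaussian curvature of the unit-area mesh (0.05 is the package's
#' fixture-scale default; see the methods vignette).
#'
#' @param cmcfIterations,cmcfDt,cmcfThresh,cmcfTmin cMCF settings.
#' @param dilationRadius reference voxelization ball (voxels).
#' @param refRemeshFraction,topoRemeshFraction remesh fractions.
#' @param refTargetVertices optional absolute reference vertex target
#'   (overrides the fraction; keeps desk-scale runs fast).
#' @param relaxEpsilon,relaxDelta,relaxRetryDelta,relaxMaxIterations
#'   area-distortion relaxation settings.
#' @param relaxCriterion stopping criterion name.
#' @param sphereDt,sphereMaxIterations conformal-flow settings of the
#'   spherical parameterization.
#' @param uvN UV grid rows (columns are 2N+1).
#' @param alpha,dIn topographic propagation settings (dOut is automatic).
#' @param gamma affinity mixing weight.
#' @param segMode \code{"bleb_filopodia"} or \code{"lamellipodia"}.
#' @param segMinSeedArea,segMinArea,segMinLabelArea,segMinComponentVoxels
#'   segmentation size filters (see \code{\link{scaleSegmentationFilters}}).
#' @param segFlatHbar,segFlatQ95 flat-surface guard thresholds (voxels).
#' @param swProjections,swRepeats sliced-Wasserstein sampling for the
#'   reconstruction report.
#' @param seed RNG seed recorded in outputs.
#' @return list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(cmcfIterations = 50L, cmcfDt = 5e-4,
                           cmcfThresh = 0.05, cmcfTmin = 1L,
                           dilationRadius = 5, refRemeshFraction = 0.9,
                           refTargetVertices = NULL,
                           relaxEpsilon = 1, relaxDelta = 0.1,
                           relaxRetryDelta = 5e-3,
                           relaxMaxIterations = 100L,
                           relaxCriterion = "equiareal",
                           sphereDt = 0.05, sphereMaxIterations = 400L,
                           uvN = 256L,
                           alpha = 0.5, dIn = 40L, gamma = 0.9,
                           segMode = "bleb_filopodia",
                           segMinSeedArea = 200, segMinArea = 500,
                           segMinLabelArea = 100,
                           segMinComponentVoxels = 500L,
                           segFlatHbar = 0.5, segFlatQ95 = 2,
                           swProjections = 50L, swRepeats = 10L,
                           seed = 1L) {
  structure(as.list(environment()), class = "PipelineConfig")
}

#' Rescale the segmentation size filters to a different voxel pitch
#'
#' The default segmentation size filters are denominated in the voxel
#' units of the validation imaging (0.104 um pitch). For data or
#' synthetic fixtures at a different physical pitch the physically
#' equivalent thresholds scale with the squared pitch ratio.
#'
#' @param cfg a \code{\link{pipelineConfig}}.
#' @param voxelSize voxel pitch of the data (um).
#' @param referencePitch pitch the default thresholds refer to (um).
#' @return the config with rescaled filters.
#' @export
scaleSegmentationFilters <- function(cfg, voxelSize,
                                     referencePitch = 0.104) {
  s <- (referencePitch / voxelSize)^2
  cfg$segMinSeedArea <- cfg$segMinSeedArea * s
  cfg$segMinArea <- cfg$segMinArea * s
  cfg$segMinLabelArea <- cfg$segMinLabelArea * s
  # the flat-surface guard thresholds target voxel-level baseline noise
  # (a resolution artifact, not a physical length) and stay unscaled
  # the component-voxel filter counts topographic voxels; it stays at its
  # default as long as the (u,v) pixel pitch is comparable to the
  # validation setting (~0.5 voxel/px)
  cfg
}

#' Run the full surface-mapping pipeline
#'
#' Executes the six steps: (1) cMCF to the automatic stop and
#' voxelization/remeshing into a genus-0 reference (skipped when
#' \code{direct} and the input is already genus 0); (2) quasi-conformal
#' spherical parameterization; (3) equiareal relaxation; (4) weighted-PCA
#' unwrapping axis and equirectangular UV grid; (5) topographic space by
#' normal propagation and resampling of the input binary; (6) topographic
#' mesh and its Cartesian remapping, with distortion and reconstruction
#' metrics.
#'
#' @param mesh closed Cartesian \linkS4class{SurfaceMesh}.
#' @param cfg a \code{\link{pipelineConfig}}.
#' @param direct skip Step 1 if the input is genus 0 (the input becomes
#'   its own reference).
#' @param segment also run the protrusion segmentation stages.
#' @param fastReference use the cMCF snapshot itself as the reference
#'   (no voxelize/remesh round; requires a clean genus-0 input).
#' @param reconstruct build the closed topographic mesh, its Cartesian
#'   remapping and the reconstruction metrics (skippable for speed in
#'   segmentation-only studies).
#' @return list bundle with all representations, reports and labels.
#' @export
runPipeline <- function(mesh, cfg = pipelineConfig(), direct = FALSE,
                        segment = TRUE, fastReference = FALSE,
                        reconstruct = TRUE) {
  bundle <- list(config = cfg, input = mesh)
  top <- surfaceTopology(mesh)
  bundle$inputTopology <- top
  # ---- Step 1: reference surface
  if (direct && !is.na(top@genus) && top@genus == 0L) {
    ref <- mesh
    bundle$cmcfStop <- 0L
  } else {
    fl <- runCMCF(mesh, flowConfig(dt = cfg$cmcfDt,
                                   maxIterations = cfg$cmcfIterations,
                                   deltaThresh = cfg$cmcfThresh,
                                   tMin = cfg$cmcfTmin),
                  stopEarly = TRUE)
    stopIt <- autoStopIndex(fl, cfg$cmcfThresh, cfg$cmcfTmin)
    bundle$cmcfStop <- stopIt
    ref0 <- flowSnapshot(fl, stopIt)
    if (fastReference) {
      ref <- ref0
    } else {
      bv <- voxelize(ref0, dilationRadius = cfg$dilationRadius)
      mt <- meshFromVolume(bv, remeshFraction = NULL)
      target <- if (!is.null(cfg$refTargetVertices)) cfg$refTargetVertices
                else round(cfg$refRemeshFraction * nrow(mt@vertices))
      ref <- remeshUniform(mt, target)
    }
  }
  refTop <- surfaceTopology(ref)
  if (is.na(refTop@genus) || refTop@genus != 0L)
    stop("reference surface is not genus 0 (residual genus ",
         refTop@genus, "); cannot unwrap")
  ref@representation <- "reference"
  bundle$reference <- ref
  # ---- Steps 2-3: sphere
  sp <- sphericalParameterize(ref, dt = cfg$sphereDt,
                              maxIterations = cfg$sphereMaxIterations)
  sp <- relaxAreaDistortion(sp, epsilon = cfg$relaxEpsilon,
                            delta = cfg$relaxDelta,
                            maxIterations = cfg$relaxMaxIterations,
                            criterion = cfg$relaxCriterion,
                            retryDelta = cfg$relaxRetryDelta)
  bundle$sphereParam <- sp
  bundle$conformalReport <- faceDistortion(ref, sp@sphere)
  # ---- reference volume, signed distance, curvature
  bvr <- voxelize(ref, dilationRadius = 1,
                  pad = max(8, ceiling(cfg$dIn * cfg$alpha) %/% 2))
  sdf <- signedDistance(bvr)
  Hvol <- divergenceMeanCurvature(sdf@data)
  d <- dim(sdf@data)
  Href <- cpp_trilinear(as.numeric(Hvol), d[1], d[2], d[3],
                        sweep(ref@vertices, 2, bvr@origin), 0)$values
  bundle$referenceCurvature <- Href
  # ---- Step 4: UV grid
  rot <- optimalRotationPCA(sp@sphere, abs(Href))
  bundle$rotation <- rot
  uv <- buildUVGrid(sp, target = ref, N = cfg$uvN,
                    rotation = rot$rotation)
  bundle$uv <- uv
  bundle$uvReport <- uvGridDistortion(uv)
  # ---- Step 5: topographic space
  inputBinary <- voxelize(mesh, dilationRadius = 1)
  space <- buildTopographicSpace(uv, sdf, alpha = cfg$alpha,
                                 dIn = cfg$dIn, dOut = "auto",
                                 enclose = inputBinary)
  bundle$space <- space
  topoBinary <- array(resampleVolume(space, inputBinary) > 0.5,
                      dim(space@coords)[1:3])
  bundle$topoBinary <- topoBinary
  # ---- Step 6: topographic meshes and reconstruction
  if (reconstruct) {
    tmClosed <- topographicMesh(topoBinary, remeshFraction = 0.2,
                                closeBottom = TRUE)
    stopo <- suppressWarnings(topoToCartesian(space, tmClosed))
    bundle$topoMesh <- tmClosed
    bundle$stopo <- stopo
    bundle$reconstruction <- compareMeshes(
      stopo, mesh, projections = cfg$swProjections,
      repeats = cfg$swRepeats, seed = cfg$seed)
  }
  if (segment) {
    bundle <- c(bundle, segmentProtrusions(space, topoBinary, cfg))
  }
  bundle
}

#' Topography-guided protrusion segmentation stages
#'
#' Runs the segmentation half of the pipeline on an existing topographic
#' space and binary: open terrain mesh, height image, ALS baseline,
#' affinity, binary segmentation, topographic curvature and instance
#' segmentation.
#'
#' @param space \linkS4class{TopographicSpace}.
#' @param topoBinary 3D logical array.
#' @param cfg \code{\link{pipelineConfig}}.
#' @return list with \code{segMesh}, \code{segMeshCartesian},
#'   \code{heights}, \code{dRef}, \code{binaryLabels},
#'   \code{instanceLabels}.
#' @export
segmentProtrusions <- function(space, topoBinary, cfg = pipelineConfig()) {
  tmOpen <- topographicMesh(topoBinary, remeshFraction = 0.2,
                            closeBottom = FALSE)
  him <- uvHeightImage(topoBinary)
  dref <- alsBaseline(him, p = 0.25, lambdaReg = 1, iterations = 10L,
                      downsample = max(2L, nrow(him) %/% 32L))
  # heights in voxels: depth indices advance in steps of alpha voxels
  ph <- protrusionHeight(tmOpen, dref)
  ph$h <- ph$h * space@alpha
  stopoOpen <- suppressWarnings(topoToCartesian(space, tmOpen))
  areas <- vertexAreas(stopoOpen)
  A <- buildAffinity(tmOpen, cfg$gamma)
  # mean height over the surface proper: the vertical cut-wall sheets at
  # the (u,v) image borders are domain bookkeeping, not surface
  dims <- dim(topoBinary)
  interior <- tmOpen@vertices[, 2] > 1.5 &
    tmOpen@vertices[, 2] < dims[2] - 0.5 &
    tmOpen@vertices[, 3] > 1.5 &
    tmOpen@vertices[, 3] < dims[3] - 0.5
  hbar <- mean(ph$h[interior])
  bs <- binarySegment(ph$h, A, areas, minSeedArea = cfg$segMinSeedArea,
                      minArea = cfg$segMinArea, hbar = hbar,
                      flatHbar = cfg$segFlatHbar,
                      flatQ95 = cfg$segFlatQ95)
  dte <- dim(topoBinary)
  phiT <- array(cpp_edt3d(!topoBinary, dte[1], dte[2], dte[3]) -
                  cpp_edt3d(topoBinary, dte[1], dte[2], dte[3]), dte)
  # smooth the distance field before differentiating: suppresses the
  # voxelization staircase that otherwise speckles the curvature
  phiT <- array(cpp_gauss3d(as.numeric(phiT), dte[1], dte[2], dte[3], 1),
                dte)
  Ht <- divergenceMeanCurvature(phiT)
  inst <- instanceSegment(Ht, topoBinary, cfg$segMode, bs, A, tmOpen,
                          areas,
                          minComponentVoxels = cfg$segMinComponentVoxels,
                          minLabelArea = cfg$segMinLabelArea,
                          seed = cfg$seed)
  list(segMesh = tmOpen, segMeshCartesian = stopoOpen, heights = ph$h,
       dRef = dref, hbar = hbar, binaryLabels = bs,
       instanceLabels = inst, topoCurvature = Ht, affinity = A,
       cartesianAreas = areas)
}

#' Per-protrusion Cartesian surface areas
#'
#' The half-maximum footprint of each instance: the Cartesian area of
#' the vertices carrying the label whose height reaches half the
#' instance's peak height. This scale-free footprint excludes the skirt
#' that label diffusion spreads onto the surrounding cortex, so the
#' areas track the physical protrusion caps.
#'
#' @param seg segmentation list from \code{\link{segmentProtrusions}}
#'   (or a \code{\link{runPipeline}} bundle).
#' @return data.frame with \code{label} and \code{area} (voxel^2).
#' @export
protrusionAreas <- function(seg) {
  inst <- seg$instanceLabels
  if (!any(inst > 0L))
    return(data.frame(label = integer(0), area = numeric(0)))
  # half-maximum footprint per protrusion: the area of the instance
  # standing above half its own peak height; a scale-free definition of
  # the protruding cap that excludes the diffusion skirt
  a <- numeric(max(inst))
  for (l in seq_len(max(inst))) {
    w <- inst == l
    if (!any(w)) next
    thr <- 0.5 * max(seg$heights[w])
    a[l] <- sum(seg$cartesianAreas[w & seg$heights >= thr])
  }
  data.frame(label = seq_len(max(inst)), area = a)
}

#' Machine-readable metrics report of a pipeline bundle
#'
#' One row per representation pair with the distortion and comparison
#' metrics; serializable to JSON/CSV.
#'
#' @param bundle result of \code{\link{runPipeline}}.
#' @return data.frame.
#' @export
metricsReport <- function(bundle) {
  rows <- list()
  addRow <- function(pair, Q = NA, lambda = NA, cd = NA, sw1 = NA,
                     dA = NA, dV = NA, quality = NA) {
    rows[[length(rows) + 1L]] <<- data.frame(
      pair = pair, globalQ = Q, medianLambda = lambda, chamfer = cd,
      slicedW1 = sw1, deltaAreaPct = dA, deltaVolumePct = dV,
      medianRadiusRatio = quality)
  }
  if (!is.null(bundle$conformalReport)) {
    r <- bundle$conformalReport
    addRow("reference->sphere", r@globalQ, r@medianLambda,
           quality = stats::median(radiusRatio(bundle$sphereParam@sphere)))
  }
  if (!is.null(bundle$uvReport)) {
    r <- bundle$uvReport
    addRow("sphere->uv", r@globalQ, r@medianLambda)
  }
  if (!is.null(bundle$reconstruction)) {
    m <- bundle$reconstruction
    addRow("topographic->cartesian", cd = m@chamfer, sw1 = m@slicedW1,
           dA = m@deltaAreaPct, dV = m@deltaVolumePct,
           quality = stats::median(radiusRatio(bundle$topoMesh)))
  }
  do.call(rbind, rows)
}
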