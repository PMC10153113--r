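# topomesh

Surface-guided computing for 3D cell biology: `topomesh` maps a closed
3D cell-surface triangle mesh — for example one segmented from a
light-sheet microscopy volume — bijectively between five
representations, and analyzes cell-surface protrusions (blebs,
lamellipodia, filopodia) in the representation where each task is
easiest:

| representation | what it is good for |
|---|---|
| Cartesian surface `S(x,y,z)` | the input; ground truth geometry |
| reference surface `S_ref` | a smooth genus-0 proxy of the cell cortex |
| unit sphere `S²` | canonical domain; guaranteed bijective charts |
| equirectangular image `S(u,v)` | 2D image processing of surface signals |
| topographic space `(d,u,v)` | protrusions become hills over a terrain |

## The models at the core

**Conformalized mean curvature flow (cMCF).** With the barycentric mass
matrix `M_t` and the cotangent Laplacian frozen at iteration 0, each
step solves

    (M_t − δt·L₀) v(t+1) = M_t v(t),

followed by surface-area normalization and recentering. Freezing `L₀`
prevents pinching and keeps the flow in the conformal class; the
reference surface is taken at the elbow of the mean absolute Gaussian
curvature trace (angle deficits), and the spherical limit of the same
flow gives a quasi-conformal, fold-free map of any genus-0 surface to
the unit sphere.

**Distortion metrics.** For each face pair the singular values
`σ₁ ≤ σ₂` of the flattened affine map give the conformal error
`𝒬 = σ₂/σ₁` (area-weighted global mean; 1 is optimal) and the
area-distortion factor `λ = (a_src/Σa_src)/(a_dst/Σa_dst)` (1 is
equiareal). An advection scheme relaxes the conformal sphere map along
`V = −∇ log λ` until the median `λ` reaches 1, with MIPS,
area-preserving MIPS and isometric stopping criteria available for
intermediate trade-offs.

**Topographic space.** The (u,v)-parameterized reference surface is
propagated along the unit gradient of its signed distance transform in
steps of `α` voxels, outward until the cell is enclosed and inward for
`D_in` steps, building a `(d,u,v) → (x,y,z)` lookup volume. Cell
binaries and intensity volumes resampled into this space turn
protrusions into hills above a terrain; heights relative to an
asymmetric-least-squares baseline drive an unsupervised instance
segmentation (curvature-seeded, diffused through a combined
geodesic/convexity affinity), with per-protrusion areas, volumes and
meshes mapped back to Cartesian space.

## Worked example

Generate a synthetic cell with 12 planted hemispherical blebs, run the
full pipeline, and read off the geometry and the segmentation:

```r
library(topomesh)

fx  <- makeFixture(fixtureSpec(baseRadius = 32, motif = "bleb",
                               k = 12, width = 0.18, seed = 112))
cfg <- scaleSegmentationFilters(
  pipelineConfig(uvN = 128, dIn = 16, cmcfTmin = 8, sphereDt = 0.1,
                 sphereMaxIterations = 200), voxelSize = 0.3)
b   <- runPipeline(fx$mesh, cfg, fastReference = TRUE)

metricsReport(b)
#>                     pair  globalQ medianLambda  chamfer deltaVolumePct
#> 1      reference->sphere 1.001609    0.9988337       NA             NA
#> 2             sphere->uv 1.564272    0.8922630       NA             NA
#> 3 topographic->cartesian       NA           NA 2.160207       1.272396

max(b$instanceLabels)
#> [1] 12
head(protrusionAreas(b), 4)
#>   label      area
#> 1     1  99.92557
#> 2     2 104.51436
#> 3     3 108.13220
#> 4     4 105.54630
```

Reading the rows: `reference->sphere` shows the spherical map is
conformal to ~0.2% (`𝒬 ≈ 1.0016`) and already nearly equiareal for this
smooth reference; `sphere->uv` shows the intrinsic distortion of the
equirectangular projection (its analytic optimum is `π/2 ≈ 1.571`);
`topographic->cartesian` shows the surface survives the round trip
through topographic space to within ~2.2 voxels Chamfer distance and
~1.3% volume error. The segmentation recovers each planted bleb as
exactly one instance label, with half-maximum footprint areas of
~100 voxel² per bleb (planted caps of angular width 0.18 rad on a
32-voxel sphere).

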