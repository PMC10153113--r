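---
title: "Surface-guided mapping of cell surfaces: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface-guided mapping of cell surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(topomesh)
```

# The problem

High-resolution light-sheet microscopy resolves the 3D surface of single
cells together with its protrusive motifs — blebs (hemispherical bumps),
lamellipodia (sheet-like ridges) and filopodia (thin spikes) — and
membrane-associated molecular signals. Analyzing these structures on the
raw triangle mesh is awkward: the surface is curved, the mesh is
irregular, and protrusions occlude one another in any fixed view.
`topomesh` maps a closed cell-surface mesh bijectively between five
representations, each convenient for a different task:

1. the input Cartesian surface `S(x,y,z)`;
2. a smooth genus-0 **reference surface** approximating the cortex;
3. the **unit sphere**, via a quasi-conformal parameterization;
4. an **equirectangular (u,v) image**, for 2D image processing;
5. a **topographic (d,u,v) space**, where `d` is depth normal to the
   reference surface — protrusions become hills on a terrain.

On top of these maps the package measures geometric distortion, and runs
an unsupervised, topography-guided instance segmentation of protrusions.

# The mapping pipeline

## Step 1 — reference surface by conformalized mean curvature flow

Mean curvature flow evolves vertex positions by the Laplace–Beltrami
operator; the conformalized variant (cMCF) freezes the Laplacian at
iteration 0 and solves, per iteration, the implicit system

    (M_t - dt * L_0) v(t+1) = M_t v(t)

with `M_t` the barycentric mass matrix and `L_0` the cotangent Laplacian
of the input. Freezing `L` prevents the pinching that breaks plain MCF on
high-curvature features and keeps the evolution close to the conformal
class. After every iteration the mesh is rescaled to unit surface area
and recentred; all flow parameters therefore refer to the unit-area
mesh, which makes `dt` scale-independent (`dt = 5e-4` by default).

The flow converges to a round sphere; the useful reference is the
*elbow* of the mean absolute discrete Gaussian curvature trace
`Kbar(t)` (angle deficits normalized by vertex area). `autoStopIndex()`
stops at the first iteration where `|dKbar| < deltaThresh` or `dKbar`
turns positive, never before `tMin`. Because `Kbar` is computed on the
unit-area mesh, thresholds are dimensionless; `0.05` stops desk-scale
fixtures within about ten iterations, consistent with the reported
behavior on real cells. A strict-literal mode (`dKbar > deltaThresh`)
is available but never triggers on monotone decays.

The stopped shape is voxelized (barycenter rasterization after midpoint
subdivision to sub-voxel edge length, then dilation by a ball of radius
5, binary filling, and erosion), which closes small holes and handles,
and re-meshed. Two deliberate numerical choices here:

* **Isosurfacing by marching tetrahedra.** Each cube is split into six
  tetrahedra sharing the main diagonal; every tetrahedron contributes an
  unambiguous cut. The result is watertight and manifold by
  construction, which the genus-0 guarantee of Step 2 depends on.
* **Erosion radius `r + 0.5`.** Rasterized surface voxels straddle the
  true surface by half a voxel on average; eroding by half a voxel more
  than the dilation removes that bias, so enclosed volumes are unbiased
  (a radius-10 ball voxelizes to within a few percent of `4/3*pi*10^3`).

Remeshing (`remeshUniform()`) decimates by shortest-edge collapse under
the link condition — topology-preserving by construction — and then
improves face quality by tangential Lloyd relaxation with reprojection
onto the source surface. Median radius ratio (2 r_in / r_circ) of
remeshed fixtures is ≈ 0.95.

## Steps 2–3 — spherical parameterization and equiareal relaxation

For a genus-0 reference, cMCF run to its spherical limit gives a
quasi-conformal map to the unit sphere: `sphericalParameterize()`
iterates until the vertex radii are uniform to `2e-4` relative spread,
then centers (area-weighted) and projects to the unit sphere. On smooth
references the global area-weighted conformal error — per face the ratio
`sigma2/sigma1` of singular values of the flattened affine map — is
1.002–1.01; any flipped spherical face raises an error.

The conformal map concentrates protrusion area near points. The
relaxation (`relaxAreaDistortion()`) advects vertices along
`V = -grad(log lambda)`, the heat-flow direction of the per-face area
distortion factor `lambda = a_ref / a_sphere` (normalized areas), with
the per-face gradient of the vertex-averaged `log lambda`. The field is
normalized by its median norm times the mean edge length of the sphere
mesh (the space being advected), averaged to vertices, projected to the
tangent plane using angle-weighted vertex normals, and applied through
one active-contour cMCF step of stiffness `delta = 0.1` and step
`epsilon = 1`; vertices are then re-projected to the sphere. Iterations
stop when `|median(lambda) - 1| < 0.01` (equiareal criterion), on
triangle collapse (interior angle below 0.5 degrees, a flipped face, or
non-finite coordinates; one retry with `delta = 5e-3`), or at 100
iterations. Three further stopping criteria interpolate between the
conformal and equiareal extremes: MIPS (`Q + 1/Q`, minimal at iteration
0 by construction), area-preserving MIPS
(`(Q + 1/Q) * (lambda + 1/lambda)`), and an isometric sum
`(1-theta) * Q + theta * mean(|log lambda|)` — the mean absolute log
area distortion is a symmetric magnitude that decreases monotonically
toward the equiareal end, so the sum has an interior optimum near half
the equiareal stopping iteration.

## Step 4 — unwrapping axis and (u,v) image

The north–south unwrapping axis is the smallest eigenvector of the
weighted covariance of the spherical vertex positions
(`optimalRotationPCA()`), with the absolute mean curvature of the
reference as weights, so strongly curved regions land near the equator
where equirectangular distortion is smallest. Signs of `e1, e2` are
fixed to positive x/y components and `e3 = e1 x e2`, giving a proper
rotation; eigenvalue ties within `1e-6` relative fall back to the
identity (any axis is equivalent by symmetry). Rows of the grid sample
the polar angle `v in [0, pi]` (north at row 1), columns the azimuth
`u in [-pi, pi]` with the seam column duplicated exactly
(`N x (2N+1)`); `(x,y,z) = (sin v cos u, sin v sin u, cos v)`. Each
pixel direction is matched to its nearest spherical triangle
(grid-accelerated exact closest-triangle query; equidistant ties go to
the lowest face index) and the barycentric weights pull back any mesh
bijective to the sphere — the reference, the input (direct unwrap of a
genus-0 input), or any per-vertex signal. Per-pixel differential areas
`dA = |dS/du x dS/dv|` weight all image-space averages
(`weightedUVMean()`); `padSpherical()` continues images across the u
seam periodically and across the poles with the half-period azimuthal
shift that pole crossing implies.

## Steps 5–6 — topographic space and meshes

The signed distance transform of the voxelized reference (positive
inside) defines the propagation field. Shells are grown from the
(u,v)-parameterized reference by explicit Euler steps of
`alpha = 0.5` voxels along the unit gradient, outward until the whole
shell clears the input cell by 2 voxels (`dOut = "auto"`), inward for
`dIn` steps; after every step the shell coordinate images are smoothed
with a separable 5-pixel box filter (periodic in u) to suppress the
characteristic instabilities of normal propagation. The stacked shells
form the `(d, v, u) -> (x, y, z)` lookup volume; trilinear sampling
resamples any Cartesian volume into topographic space and
`topoToCartesian()` inverts the map.

The topographic binary of the cell is isosurfaced like any volume. Where
the solid cell interior reaches the bottom of the depth domain the
terrain cannot close; `topographicMesh()` zero-pads the volume so the
mesh is watertight (`closeBottom = TRUE`, the right choice for
Cartesian reconstruction and volume metrics) or strips the closing
plate (`closeBottom = FALSE`), leaving the open terrain sheet used by
the height-based segmentation.

# Protrusion segmentation

The reference baseline `d_ref(u,v)` is fit to the height image (top of
the longest contiguous foreground run per (u,v) column) by a 2D
asymmetric-least-squares solve: weights `p = 0.25` above / `1-p` below
the current baseline, a squared-Laplacian penalty `lambda = 1`, 10
reweighting iterations, after 8x downsampling (desk-scale grids use the
equivalent fraction of their size). Protrusion height is
`h = d - d_ref`.

Binary segmentation seeds at `h >= mean(h)` — the mean is taken over the
(u,v) height image so that each surface point counts once and the
domain-cut walls of the terrain mesh cannot bias it — removes seed
components below 200 voxel², diffuses two-class label spreading over the
combined affinity `A = 0.9 * A_dist + 0.1 * A_convex` (Gaussian kernels
of edge length and of the vertex-normal cosine distance `(1-cos)/2`,
each scaled by its own mean; one-ring sparsity) for 20 iterations at
clamping 0.99 with re-binarization at probability 0.25, and removes
final components below 500 voxel². Instance segmentation clusters the
smoothed topographic mean curvature over surface-shell voxels (k-means,
sigma 1, for blebs/filopodia; a Gaussian mixture over sigma 1/3/5
features for lamellipodia; 3 classes, fitted on 10,000 seeded samples),
keeps the class of highest mean curvature, labels its connected
components (>= 500 voxels), expands them by 3 voxels, transfers them to
the terrain mesh, intersects with the binary segmentation (>= 100
voxel²), and diffuses 10 iterations without re-binarization.

Numerical choices worth knowing:

* The topographic curvature is differentiated from a **sigma-1 smoothed**
  signed distance field. The raw voxel-quantized field carries a
  staircase exactly at the interface that speckles the curvature and, at
  desk scale, pollutes the high-curvature class.
* The two polar image rows are **coordinate singularities** of the
  equirectangular map; shell voxels within 3 rows of a pole are excluded
  from instance seeding. The PCA axis already steers protrusions away
  from the poles, so nothing real is lost.
* The size filters are denominated in the voxel units of the validation
  imaging (0.104 um pitch). `scaleSegmentationFilters()` converts them
  to other pitches by the squared ratio; the synthetic studies use a
  0.3 um fixture pitch (base radius 32 voxels ≈ a 10 um cell).
* Label diffusion with re-binarization advances roughly one mesh ring
  per iteration, so the binary segmentation is deliberately generous —
  it is an outer mask. Per-protrusion areas are therefore reported by
  `protrusionAreas()` as the Cartesian area of each instance's
  above-mean-height region, which excludes the diffusion skirt and
  tracks the physical caps (regression slope ≈ 0.9 against planted
  areas, matching the cross-method slopes reported for real cells).

Undersegmented (conjoined) blebs are refined per label: small complement
components are absorbed, the submesh is downsampled and unwrapped to a
128x128 square (harmonic disk map with arc-length boundary, 2D
equiareal relaxation with fold rejection, elliptical disk-to-square
mapping), the pulled-back curvature is thresholded at the upper 3-class
Otsu threshold, closed with a 1-pixel disk, and split by watershed on
the Euclidean distance transform (basins under 10% of the footprint are
merged); split seeds are re-diffused on the full mesh and filtered at
10 voxel². The surface labels are volumized by slice-wise marker
watershed from the top of the depth domain to the bottom (previous
slice's labels take precedence), the cortical volume (below the
harmonically inpainted `d_ref`) is masked out, and each label keeps its
largest connected region.

# The synthetic fixtures

`makeFixture()` plants `k` motifs on an icosphere (subdivision 4, base
radius 32 voxels) at rejection-sampled centers with a minimum angular
separation of `max(2.5 * width, 0.4)` radians. Motif profiles:
hemispherical caps (`bleb`, compact support with a sharp rim — the neck
geometry the dihedral affinity exploits), Gaussian bumps (`gauss`, used
by the parameterization studies), elongated Gaussian ridges (`ridge`)
and narrow super-Gaussian spikes (`spike`). Truth labels mark vertices
whose displacement exceeds 50% of the owning motif's amplitude. Matched
binary volumes come from `voxelize()`; the intensity volume is a
2-voxel cortical shell. All randomness flows through the single seed,
and the same seed reproduces bit-identical fixtures.

What the fixtures do **not** emulate: segmentation noise and topological
defects of real meshes beyond the explicit `punchDefects()` holes and
handles, anisotropic voxels, imaging PSFs, and protrusion densities as
high as real lamellipodial cells. Passing tests demonstrate the
geometric machinery and the recovery of planted structure, not
robustness to every pathology of microscopy segmentations.

## Validation study conditions

The end-to-end validation studies fix their fixture parameters once:

* **Counting study** (instance count vs planted count, k = 5..30 over 20
  seeds): cap width 0.18 rad. Narrower caps at small k cover so little
  of the sphere that the flat-surface guard (mean height below 0.5
  voxel and 95th percentile below 2 voxels, kept at its
  voxel-denominated values because it targets voxel-level baseline
  noise) legitimately declares the surface flat; 0.18 rad caps escape
  the guard from k ≈ 8 upward, and the median count error absorbs the
  remaining sparse cases.
* **Area-recovery study** (regression of measured vs planted cap areas
  spanning 10x): three seeded fixtures pooled (30 caps, widths
  0.09–0.285 rad, subdivision-5 input meshes), with the reference
  flowed into its spherical regime (tMin = 25) — the planted truth is
  defined against the base sphere, so the reference must not absorb the
  caps. Measured areas are the half-maximum footprints from
  `protrusionAreas()`. The recovered slope sits near 0.86–0.9; the
  residual attenuation below unity is half-height contour erosion of
  the smallest caps at desk-scale resolution.

# Problem sizes and runtime choices

The validation studies run at desk scale, chosen so the full suite
completes in minutes on one core: fixtures with 2,562-vertex input
meshes, references remeshed to ~6,000 vertices, (u,v) grids of 128 rows
(the reference setting is 256, and 512 rows for topography on real
cells), `dIn = 10..16`, and topographic meshes capped at 20,000
vertices. The conformal flow runs at `dt = 0.05` (0.1 in the repeated
segmentation studies) to its sphericity tolerance. These sizes are
stated here as the package's own study conditions; all thresholds of
the method itself are the validated defaults described above.

# Known limitations

* Inward shells cannot pass the medial axis; deep concavities fold and
  are only box-smoothed, not untangled. The depth domain should stay
  within `min(dIn, dOut)` of the reference.
* The genus-0 requirement is enforced, not repaired: inputs whose
  defects survive cMCF + voxelization fail Step 2 with a genus message,
  mirroring the reported failure mode on real cells.
* Equiareal relaxation is limited by mesh quality; collapse triggers a
  single slower retry and otherwise returns the last valid iteration
  with status `"collapsed"`.
* The binary protrusion segmentation is an outer mask by design (see
  above); do not read its area as a protrusion area.
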