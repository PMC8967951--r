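---
title: "spineflow: models, algorithms, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{spineflow: models, algorithms, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spineflow)
```

# The problem

Dendritic spines are micrometer-scale protrusions of cortical dendrites
and the main postsynaptic targets of excitatory synapses. Segmenting
them from confocal stacks is hard for two reasons: spine necks are often
thinner than the optical resolution limit, and expert reconstructions
(the training ground truth) are weakly annotated -- entire branches may
be left unreconstructed, and structures traced with several intensity
iso-surfaces can fall apart into unattached components.

`spineflow` implements a complete volumetric workflow around these
problems: ground-truth voxelization from closed surface meshes,
automatic reconnection of detached parts, weighted loss functions for a
3-class (background / dendritic shaft / spine) encoder--decoder
segmentation network, user-parameterizable postprocessing, and a
synthetic phantom generator that serves as the test bed for every other
module.

All physical quantities are in micrometers. The default voxel geometry,
`0.0751562 x 0.0751562 x 0.279911` um, is the confocal spacing the
workflow was designed around; grids are stored as R arrays with dim
`(nx, ny, nz)` (x fastest -- the same memory layout as a pages-first
TIFF stack), while every API speaks `(x, y, z)`.

# Voxelization of surface reconstructions

Closed shaft and spine meshes are converted to label volumes in two
steps (`rasterize_surface()`, `fill_interior()`):

1. every voxel whose box intersects a mesh triangle is marked, using an
   exact triangle/box separating-axis test rather than centroid
   sampling, so thin triangles crossing a voxel corner are never missed;
2. the interior is recovered by labeling the 6-connected components of
   the complement and marking those that do not touch the volume
   border. This is robust to coincident faces, where parity ray casting
   fails.

A voxel is the half-open box `[i, i+1) * voxel_size + origin`; a face
lying exactly on a boundary plane belongs to the voxel on the positive
side. When shaft and spine claims overlap the spine wins
(`voxelize_scene(..., spine_over_shaft = TRUE)`): spine surfaces are
traced over the shaft in the source reconstructions and spine identity
is the analysis target. Per-spine provenance is kept in an attached
instance volume so no identity is lost to the 3-code label scheme.

**Known bias.** Because *every* box the surface touches is marked, the
filled voxel set is the outer Jordan cover of the solid. By the Steiner
formula its volume exceeds the true volume by roughly `S * h` (surface
area times mean half-voxel extent) -- about +22% for a sphere of radius
10 voxels, halving as resolution doubles. This is a property of the
marking rule itself, not of the implementation; volume statistics read
off voxelized ground truth inherit it, which matters for thin
structures like necks. The error-halving behaviour is verified in the
test suite.

# Automatic reconnection of detached structures

The preprocessing stage repairs unattached components with a five-step
procedure per structure: clipping to the padded bounding box, connected
component detection, A* path search, median denoising, and tolerance
flood fill.

The path objective is

$$\min_{p \in P}\; \sum_{i=1}^{\#p} (1 - \mathrm{den}(p_i))\, f_s \;+\;
\sum_{i=2}^{\#p} \mathrm{dist}(p_{i-1}, p_i),$$

where `den` is the min--max normalized image intensity over the clip,
`dist` the voxel center distance, and admissible paths may not cross
other anatomical structures. The defaults are the published working
values: `f_s = 1`, an `8 x 8 x 2` voxel median mask, 10% flood
tolerance, maximum ellipsoid masks of `3 x 3 x 2` voxels for shaft
connections and `6 x 6 x 2` for spines, minimum `1 x 1 x 0`.

Design points that were genuinely open:

* **Distance units.** The objective's length term defaults to physical
  um, honoring voxel anisotropy; a voxel-unit mode is kept for
  ablation. The path was reported to be insensitive to `f_s`, so either
  scale is defensible; physical units are the principled choice.
* **Heuristic.** A* uses the Euclidean distance transform to the target
  set as heuristic. Every density term is non-negative and the length
  term dominates the straight-line distance, so the heuristic is
  admissible: the returned cost equals an uninformed Dijkstra search's
  (verified against an independent `igraph` oracle on hundreds of
  random instances).
* **Ellipsoid masks** are read as per-axis semi-axes in voxels with
  membership `(dx/a)^2 + (dy/b)^2 + (dz/c)^2 <= 1`; a zero semi-axis
  means no growth along that axis, which is what makes `1 x 1 x 0`
  purely in-plane.
* **Median window anchoring.** Even-sized windows take the extra extent
  toward the positive axis; borders reflect. The filter runs once per
  clip, after path finding, matching the stage ordering.
* **Per-seed tolerance.** Each path voxel floods against its own
  filtered intensity (plus/minus the tolerance fraction), rather than a
  single global band.
* **Traversal order.** Components are visited largest-first with the
  largest as anchor; the loop stops at one component or at the first
  full pass without progress (each success must reduce the component
  count, which guarantees termination).

`preprocess_ground_truth()` composes three passes: shaft self-repair,
per-spine fragment repair (when instance provenance is available), and
attachment of loose spine components to the shaft, where shaft voxels
and already-attached spines are valid targets and connector voxels take
the spine class. The procedure only ever adds voxels, and running it
twice equals running it once.

# Weighted losses

The weighted cross-entropy loss is
$\mathrm{WCEL} = -\sum_x w(x) \sum_k r_k(x) \log p_k(x)$ with
$w = w_\mathrm{class} \cdot w_\mathrm{pixel}$. Class weights use the
smoothed form $w'_k = \max(\log(2\,\#\Omega/\#k),\, 1)$, normalized to
sum to one. Two distance-based pixel weightings de-emphasize voxels far
from any annotation (where "background" may actually be an
unreconstructed branch): `(1 - r_decay)^d` and the compact window
`(1 - (d/d_max)^2)^2`, with `r_decay = 0.5` and `d_max = 5` um as
defaults and `d` the exact anisotropic Euclidean distance field in um.
The generalized Dice loss with inverse-squared-volume class weights is
provided as the alternative objective.

Decisions the formulas leave open: the logarithm is natural throughout;
an absent class takes the single-voxel limit `log(2 #Omega)` in the
smoothed scheme (patches without spines are common and must train) and
weight zero in the Dice scheme (removing it from both sums, the usual
epsilon-guard policy); `log` is clamped at `p = 1e-12` so confident
wrong predictions stay finite.

# The segmentation network

`build_model()` constructs a 3D U-Net-style encoder--decoder: `stages`
resolution levels, two `3^3` convolutions + ReLU per level with channel
doubling, max-pool downsampling, transposed-convolution upsampling with
center-cropped skip connections, and a final 3-class softmax. The
published configuration is 5 stages, 16 base channels, input patch
`300 x 300 x 66`, output patch `116 x 116 x 10` with valid
convolutions.

That patch contract pins down the pooling schedule: with two valid
`3^3` convolutions per level, `300 -> 116` requires pooling x and y at
every level, and `66 -> 10` is realizable exactly by pooling z only at
the second level (`1, 2, 1, 1`). `unet_config()` solves the per-axis
schedule automatically and rejects impossible contracts with the
achievable alternatives. The receptive-field margin `(92, 92, 28)` is
exposed via `unet_margins()`.

Training uses Adam (`beta1 = 0.9`, `beta2 = 0.999`, `epsilon = 1e-7`).
The configuration stores the published learning rate `1e-7` as the
default profile; desk-scale runs use `1e-3` (an Adam step of `1e-7` is
unusually small, but the published value is not silently replaced).
Patches are tiled with stride equal to the output patch (complete,
non-overlapping coverage; the last tile clamps to the border), input
windows are expanded by the margin with reflective padding, and two
labeled-content filters are provided: `any_labeled` (the M1/M2 rule)
and `min_fraction` with the 10% threshold (the M3 rule). Augmentation
draws from the isometries that keep voxel-to-voxel correspondence:
axis flips, in-plane quarter-turn rotations, and small integer-voxel
translations, applied identically to image, labels, and weights.
Validation-based model selection keeps the parameters with the best
masked mean F1 (the published criterion names only "smallest validation
error"; masked mean F1 is this package's reading).

Same-mode convolutions pad reflectively by default (zero padding is
available via `padding_mode`); zero padding imprints patch borders on
every feature within the receptive field, which hurts precisely the
desk-scale regime where patches are small, whereas mirrored borders
resemble real content and transfer to full-volume prediction.

Prediction tiles the volume with stride equal to the output patch. For
valid-convolution models the input margin supplies the context; for
same-convolution models each tile additionally receives a
pooling-aligned receptive-field context margin (the classic
overlap-tile strategy), which makes the tiled result exactly equal to
an untiled run and independent of tile order. Inputs are scaled by
1/65535 (fixed 16-bit range) at both training and prediction time.
Evaluation restricts metrics to voxels within 7.58 um of the
ground-truth shaft -- the maximum spine-to-shaft distance in the source
data -- and reports per-class precision, recall, F1, and their mean.

# Postprocessing

* `remove_noise()` deletes a disconnected component only when it is
  both farther than `D` from every shaft component larger than `V_d`
  AND smaller than `V_s` (defaults 3 um, 0.16 um^3, 0.024 um^3). The
  distance argument is read as the component being tested (the
  published formula's argument is taken as a typographical slip for the
  component), and sizes are physical um^3 since the thresholds are
  printed in um^3. Component distance is the minimum voxel-center
  distance.
* `watershed_split()` performs marker-based watershed restricted to the
  instance mask. The relief defaults to the negated anisotropic
  distance transform of the mask, which splits touching spines at neck
  constrictions; a raw-intensity relief is available via argument. Ties
  are broken by queue insertion order, making the split deterministic.
* `mesh_from_labels()` extracts per-instance iso-surfaces at level 0.5
  with vertices in um. The surface is built by splitting each cell of
  eight voxel centers into six tetrahedra (Kuhn subdivision, consistent
  across neighboring cells) and triangulating each tetrahedron against
  the level -- the marching-tetrahedra variant of marching cubes. This
  variant has no ambiguous configurations, so meshes of instances away
  from the volume border are watertight by construction; the price is
  roughly twice the triangle count of table-based marching cubes. No
  smoothing is applied (geometry fidelity first).
* `count_unconnected_spine_parts()` implements the connectivity
  statistic used to quantify preprocessing impact: among predicted
  spine components overlapping ground-truth spines, those with no voxel
  26-adjacent to predicted shaft; `improvement_ratio()` turns
  before/after counts into the reported percentages.

# The phantom generator

`generate_phantom()` produces the study conditions for every scaled
experiment: a `64 x 64 x 32` volume at confocal spacing
(4.8 x 4.8 x 9.0 um) containing a tubular shaft of radius 0.45 um
around a smooth random centerline, nine spines with head radii
0.20--0.34 um on cylindrical necks of radius 0.10 um (deliberately at
the resolution limit) and length 0.4--0.9 um. The intensity channel is
the structure indicator at 40000 of the 16-bit range, convolved with a
separable Gaussian PSF of sigma `(0.09, 0.09, 0.27)` um -- the 3x axial
elongation mimics the confocal point-spread function implied by the
anisotropic voxel -- plus Gaussian read noise of sigma 1200 (3% of
peak). These values were chosen once as a realistic bright, well-imaged
preparation and are not tuned per experiment.

Two annotation defects can be injected. `break_necks` erases, for
selected spines, the labeled voxels within 0.35 um of the shaft --
detaching the spine while leaving the image intact, exactly the
unattached-component defect. `missing_branch` adds a collateral branch
to the intensity but not the labels (the missing-reconstruction
defect); it defaults off, so the default phantom is a fully
reconstructed field of view, and tests that need the defect enable it.

What the phantom does *not* emulate: real fluorophore statistics
(Poisson noise is available but off by default), uneven staining,
mushroom/thin/stubby spine shape families, overlapping spines from
neighboring dendrites, and depth-dependent attenuation. Passing tests
on phantoms therefore demonstrate correctness of the algorithms under
controlled conditions, not clinical-grade performance on human-cortex
stacks.

# Scaled-down experiments

Because full-scale training needs GPU-class hardware and the original
annotated data set, the package validates its training stack at desk
scale; the sizes below are the package's chosen study conditions.

* **Reconnection recovery**: 20 phantoms with neck-break probability
  0.5; `preprocess_ground_truth()` is expected to reattach at least 90%
  of broken spines and never disconnect intact ones. Measured: 100%
  across the default seeds.
* **Segmentation capacity**: a tiny U-Net (2 stages, 8 channels,
  same-convolution with reflective padding, `32 x 32 x 16` patches,
  pool `(2, 2, 1)`, Adam at `1e-3`, batch size 1, 15 epochs, no
  augmentation, any-labeled patch filter) trained on 8 clean phantoms
  and evaluated with its final-epoch parameters. The anisotropic
  pooling keeps the already-coarse z axis at full resolution;
  augmentation is off because held-out phantoms come from the same
  generator, so the convergence cost of augmentation noise buys nothing
  within the epoch budget. Held-out spine F1 is about 0.8 under the
  default seed.
* **Preprocessing impact replay**: two identical networks trained on
  corrupted vs preprocessed labels of 4 broken phantoms (8 epochs),
  compared by the unconnected-predicted-spine-part count on 2 held-out
  phantoms. The direction (fewer unconnected parts after preprocessed
  training) is stochastic at this scale and is reported rather than
  gated.

# Known limitations

* The voxelizer's outer-cover volume bias (above) is inherent to the
  surface-inclusive marking rule.
* The A* search is exact but explores the full clip in the worst case;
  very large detached structures pay accordingly (clipping keeps the
  common case small).
* Same-convolution models see reflect-padded patch borders during
  training but real context at prediction; the residual mismatch is
  confined to a border shell of the training receptive field.
* The training loop is plain R orchestrating BLAS-backed C++ kernels:
  adequate for the desk-scale experiments it exists to support, not a
  GPU substitute.
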