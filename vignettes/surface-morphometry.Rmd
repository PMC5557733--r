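---
title: "Surface-based morphometry of the rodent mandible with mandmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface-based morphometry of the rodent mandible with mandmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mandmap)
```

## The problem and the model

Diet-consistency experiments in mice (soft powdered diet versus hard
pellets) produce subtle, spatially localized changes in mandibular shape.
Classical 2D cephalometry reduces the mandible to a handful of linear and
angular measurements and misses most of this signal. mandmap implements a
surface-based alternative: each specimen's micro-CT scan is segmented to a
bone surface, standardized into a landmark-defined coordinate frame, and
re-expressed as a *homogeneous model* — a fixed-topology template mesh of
12,186 nodes fitted to the specimen so that node *i* denotes the same
anatomical locus in every animal. Group comparison then reduces to
per-node statistics on corresponding coordinates:

* the **averaged model** of a group is the per-node arithmetic mean of
  coordinates (with per-node, per-axis sample SD),
* the **difference map** is the per-node, per-axis difference of two group
  averages (mm),
* the **significance probability map** applies an independent two-sided
  two-sample *t*-test to every node and axis (pooled-variance Student's
  *t* by default; Welch optional), banding the uncorrected p-values at
  0.05 / 0.01 / 0.001 / 0.0001,
* the **accentuated average** linearly extrapolates a group average away
  from a reference, `ref + k (grp - ref)`, to make subtle phenotypes
  visible, and
* the **region summary** collapses the maps into a table of
  (region, surface, axis) cells with direction words (Inward/Outward,
  Upward/Downward, Forward/Backward) and significance stars.

The axes of the standardized frame are anatomical: x transverse
(+x lateral for a right hemimandible), y vertical (+y superior),
z antero-posterior (+z posterior). Direction words translate the sign of
a mean displacement through this convention; "Forward" is therefore a
negative z displacement.

## Segmentation

Bone is segmented from the micro-CT volume by a seeded GrowCut cellular
automaton: labelled seed voxels carry strength 1 and iteratively "attack"
their 26-neighbourhood; a voxel adopts an attacker's label whenever the
attacker's strength, attenuated by the intensity contrast
`g(x) = 1 - x` on range-normalised intensities, exceeds its own. Updates
are synchronous and the automaton provably converges on finite grids
(strengths are bounded and non-decreasing). Erosion/dilation with discrete
ball structuring elements and largest-component selection provide the
usual cleanup, and an isosurface at level 0.5 yields the triangulated
surface in mm.

Two numerical choices deserve note:

* **Isosurface extraction** uses tetrahedral marching on the uniform Kuhn
  (6-tetrahedron) cube decomposition. Every cube is split identically, so
  shared faces carry the same diagonal and the mesh is watertight by
  construction, with orientation fixed per-triangle against the inside of
  the field.
* **Pre-smoothing sigma defaults to 1.0 voxel.** On an analytic sphere
  phantom, tetrahedral marching on the raw binary mask leaves diagonal
  lattice artifacts that inflate surface area by roughly 10%; Gaussian
  pre-smoothing with sigma 1.0 voxel brings area within 0.1% and enclosed
  volume within about 1% of the analytic values, while sigma 0.5 is not
  enough to suppress the artifact. Sigma is configurable and 0 disables
  smoothing (used, e.g., when extracting a single voxel, which a
  midpoint-interpolating isosurface encloses with volume between
  spacing^3/6 and spacing^3 — not spacing^3).

## Coordinate standardization

Growing-mouse superimposition needs a reference that bone modelling does
not move. The frame places the origin at the **mental foramen**; the
y-axis is the unit normal of the least-squares plane through the six
molar-cusp (occlusal) landmarks, signed so the coronoid tip is superior;
the z-axis is the in-plane direction from the mental foramen towards the
condyle centre (posterior positive); x completes the right-handed frame.
Which landmarks play these roles is data, not code: landmark sets carry a
`roles` attribute, and the default schema's roles (`default_frame_roles()`)
are used as a fallback.

Two consequences of this construction matter for the statistics. First,
applying any rigid motion to all inputs cancels exactly, so maps are
invariant to specimen pose (verified to 1e-9 in the tests). Second, some
coordinates are *pinned by construction* — the origin landmark exactly,
and the condyle centre's transverse coordinate, which the frame definition
zeroes. Across specimens these coordinates vary only at floating-point
rounding level, so the significance map classifies a node-axis as
zero-variance whenever its standard error is below 1e-12 times the
coordinate scale (equal means give p = 1; unequal means are flagged
degenerate with no category rather than being epsilon-floored into fake
significance). Genuine simulated shape noise is at least a millionth of a
millimetre at every node, three orders of magnitude above this cut.

## Homogeneous modelling

The template fit has two stages. A 3D thin-plate spline with kernel
U(r) = r, built on the 69 landmark pairs (template anchors to specimen
landmarks), initialises all template nodes; `lambda` adds diagonal
regularization (default 0 = exact interpolation; the bordered system is
solved with one step of iterative refinement, and distance evaluation uses
the difference form to avoid cancellation near the landmarks). Then
`n_iters` (default 3) iterations alternate exact closest-point projection
onto the target surface with one umbrella-smoothing pass (weight 0.5) of
the *displacement field relative to the warped reference*, keeping
landmark-anchor nodes pinned on their landmarks. Smoothing displacements
rather than positions makes the template an exact fixed point of fitting
to its own surface, and pinning keeps fitted models superimposable at the
mental foramen. Closest-point queries use exact point-triangle distance
under a uniform grid with expanding-shell search; distance ties keep the
lowest triangle index, so fits are deterministic.

On noise-free synthetic targets the fit recovers a known smooth
deformation with RMS error below 0.001 mm per node — well inside the
0.02 mm recovery budget used by the acceptance tests — and the mean
node-to-surface residual decreases monotonically over iterations.

## The synthetic hemimandible

Because no scan data accompany the design, every stage is validated on a
parametric hemimandible. The template is a closed genus-0 surface: a
superellipsoid-like body (semi-axes 0.6 x 1.4 x 5.3 before scaling)
plus smooth Gaussian bumps for the coronoid, condylar and angular
processes, the antegonial notch, the alveolar ridge, three molar cusps,
the masseteric ridge, a medial fossa and the incisal region; the result
is rescaled to 12 mm overall length (mouse scale). Node placement
distributes a configurable budget (default 12,186) over latitude rings in
proportion to ring circumference and stitches adjacent rings with a
zipper triangulation, giving a closed 2-manifold for any budget of at
least 100 nodes. The proportions were fixed once so that the default
template reproduces the published design constraints: 12,186 nodes,
69 landmarks, about 12 mm length, and a mean inter-node edge length
(0.0915 mm) below the 0.096 mm micro-CT voxel size that defines mesh
adequacy. The template covers a *single* (right) hemimandible rather than
a mirrored full mandible: the published table reports right halves
separately, and a one-sided template keeps the 69-name schema and node
correspondence unambiguous; left-side specimens can be reflected with
`mirror_x()` when pooling is wanted (off by default).

Regions (coronoid process, condyle, alveolar process, inferior body,
angular process, antegonial notch, molars) are labelled on template nodes
from the bump geometry and transfer to every fitted model by node index;
surface classes (lateral/medial/anterior/posterior/superior/inferior and,
for molars, occlusal/labial/lingual) come from outward vertex normals.

**Effect fields** encode ground truth: a per-region displacement vector
with weight 1 on the region's nodes and a Gaussian falloff (default width
1.5 mm, a regional scale of about an eighth of the mandible) of the
distance to the region outside it. The falloff means an injected effect
genuinely displaces adjacent regions at reduced amplitude — tests that
check recovery account for this rather than pretending neighbouring cells
are null.

**Shape noise** is modelled as a statistical shape space: 12 study-level
Gaussian radial modes (width 2 mm) centred on random template nodes, with
independent per-specimen N(0, noise_sd^2) loadings per mode and axis
(defaults: noise_sd 0.1 mm, landmark jitter 0.05 mm). Sharing the mode
basis within a study and drawing independent loadings per specimen keeps
specimens independent and makes per-node coordinates exactly Gaussian
across specimens, so the per-node *t*-test is exactly calibrated under
the null — which the 200-replicate type-I calibration in the acceptance
suite confirms empirically (mean per-replicate flag rate at 0.05 within
three standard errors of 0.05, with the replicate mean absorbing the
strong spatial correlation the shared modes induce). What this generator
does *not* emulate: anatomically accurate mouse geometry, CT physics
(beam hardening, partial volume), correlated left-right asymmetry, or
digitization bias in landmarks — so green tests certify the pipeline's
statistical and geometric machinery, not biological findings.

Rasterization closes the loop for segmentation testing: a closed mesh is
voxelized by parity counting along scan columns (voxel centres at
`origin + (index + 0.5) * spacing`, 0-based, default spacing 0.096 mm),
with configurable foreground/background intensities and seeded Gaussian
noise.

## Reporting conventions

The difference map is computed as group A minus group B; the published
figure convention is HD minus SD (red where the control is larger), so
`run_study` writes maps as A - B with A the first-listed (HD) group,
while the region summary table follows the "SD compared with HD"
convention and is built from B - A. In a region-summary cell, "NS" means
no node reached p <= 0.05; otherwise the direction word comes from the
sign of the mean displacement over the cell's significant nodes, and the
stars show the strongest threshold attained by at least 5% of the cell's
nodes (minimum one star). The 5% cell rule is this package's choice: the
published table does not state how per-vertex p-values were collapsed
into cells. No multiple-testing correction is applied by default, to
reproduce raw per-vertex probability maps; Benjamini-Hochberg across
nodes within an axis is available behind the `fdr` flag, and the Welch
test behind `variant = "welch"`.

The accentuation coefficient defaults to k = 2; the exact coefficient
used in the original figures is not published, so accentuated outputs
should be read as a visualization device, not a reproduction.

## Problem sizes used in the tests

The test and acceptance suites run entirely on synthetic data at sizes
chosen to exercise every code path quickly: the full 12,186-node template
for the node-count, resolution, effect-recovery and segmentation-phantom
checks (16 template fits take about 20 s); a 2,000-node template for the
200-replicate null calibration; 800-1,500-node templates for property
tests; 20^3 phantoms for the brute-force GrowCut and morphology oracles.

## Known limitations

* The fit is landmark-initialised template morphing; it assumes the
  landmark warp already brings nodes near their anatomical targets and
  will slide correspondence tangentially where landmarks are sparse.
* GrowCut quality is phantom-validated; the original study's manual
  editing and parameters are unrecorded, so real-scan segmentation should
  be reviewed visually.
* Per-vertex uncorrected p-values reproduce the published maps but carry
  the usual multiplicity caveat; use the FDR flag for inference beyond
  map reproduction.
* Cortical-bone and cartilage thickness, interior structure, and
  volumetric statistics are out of scope: only the outer surface is
  analysed.
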