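---
title: "Threshold sensitivity of bone surface models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threshold sensitivity of bone surface models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Craniofacial change over time is commonly assessed by superimposing serial
3D radiographic scans (CT or cone-beam CT) on the anterior cranial base, a
structure whose form is stable from early childhood. The bone surface model
used for that superimposition is usually segmented with a **single grey
intensity threshold**: every voxel above the threshold is bone, the
isosurface at the threshold is the model. The threshold is picked by
software or adjusted by an operator, so the obvious question is how much
the resulting surface model — and everything downstream of it — depends on
that choice. `threshsurf` implements the full sensitivity analysis: a
reference threshold estimated from the data, a family of offset
thresholds, surface extraction at each, best-fit superimposition, distance
and movement metrics, and permutation-based statistics, exercised
end-to-end on synthetic phantoms with analytic ground truth.

## The reference threshold

Given a voxel labelling of the structure (structure vs surround), the
**interface voxels** are those of either class with at least one neighbour
in the opposite class; voxels completely surrounded by their own class are
discarded. Because a voxel that straddles the bone boundary averages the
two tissues (the partial-volume effect), interface voxels carry
intermediate intensities, and their arithmetic mean is taken as the
*reference threshold* for that scan:

```{r}
rt <- reference_threshold(volume, mask, connectivity = 6)
```

Design points:

* **Connectivity.** "At least one neighbour" is read minimally as the six
  face neighbours; `connectivity = 26` widens it to face+edge+corner
  neighbours. The interface set is symmetric in the class labels, and the
  6-connected set is a subset of the 26-connected one.
* **Grid border.** Out-of-grid neighbours are ignored rather than treated
  as the opposite class.
* **Intensity scale.** Volumes are windowed (`intensity_window()`) and
  affinely rescaled to 0–1000 (`rescale_volume()`); values outside the
  window are clamped (deterministically, with a report) rather than
  dropped. The same affine map applies to scalar thresholds
  (`rescale_threshold()`), and the two commute: estimating the threshold
  then rescaling equals estimating on the rescaled volume, provided no
  interface voxel is clamped. The 0–1000 scale is treated as continuous;
  nothing is re-quantised to integers.

On a noise-free two-material phantom the estimator recovers the
mid-intensity `(soft + bone) / 2` up to a curvature-and-discretisation
bias of a few units (see the acceptance script), which shrinks as the
grid refines.

## The threshold family and surface models

`threshold_set(reference)` builds the seven values
`reference + {-60, -40, -20, 0, +20, +40, +60}` (step and count are
parameters; all values must stay within 0–1000). At each value an
isosurface is extracted:

* `extract_isosurface()` uses **marching tetrahedra** on the Kuhn
  6-tetrahedra subdivision of each grid cell — a topology-consistent
  marching-cubes variant. Every output vertex lies on a cell edge whose
  endpoint samples bracket the iso value and is placed by linear
  interpolation; using the same cell diagonal everywhere makes face
  diagonals agree between neighbouring cells, so the mesh is
  watertight where the level set stays inside the grid. The variant name
  and iso value are recorded in the mesh's provenance attribute.
* No smoothing or decimation is applied — the surface models are the raw
  isosurfaces.
* `crop_mesh()` restricts the analysis to a region of interest selected
  on the reference model (an axis-aligned box or an explicit vertex
  mask). The rule is deterministic: a face survives only if all three of
  its vertices lie in the ROI; optionally only the largest connected
  component is kept. For phantoms the default ROI is the upper part of
  the outer dome, the analogue of selecting the upper surface of the
  anterior cranial fossa floor.

## Superimposition and metrics

Each offset model is compared with the reference model three ways,
mirroring the workflow the analysis quantifies:

1. **MAD before superimposition** — `mean_absolute_distance()` takes, for
   every vertex of the moving mesh, the Euclidean distance to the exact
   closest point on the reference surface (triangle interior, edge or
   vertex — not the nearest vertex, which would inflate distances at CT
   vertex densities), and averages. The metric is directed; the pipeline
   always measures threshold model → reference. Queries go through an
   axis-aligned-bounding-box hierarchy with exact leaf tests, so results
   are identical to an exhaustive scan over all triangles.
2. **Movement for best fit** — `icp_register()` runs point-to-plane ICP:
   exact closest-point correspondences each iteration, minimising
   `sum(((R p + t - q) · n_q)^2)` via the small-angle linearisation,
   re-orthonormalised with Rodrigues' formula so the accumulated
   transform is exactly rigid. Defaults mirror the workflow under study:
   100% assumed overlap, 100% point sampling, exact nearest-neighbour
   search, 50 iterations, no early exit (a tolerance-based stop exists
   but is off by default). Initialisation is the identity — threshold
   models from the same scan start near-aligned. The result is
   decomposed (`decompose_transform()`) into three translations and three
   rotations about the reference-mesh centroid, in the anatomical frame
   x lateral (+right), y anteroposterior (+posterior), z vertical (+up).
   Euler order is intrinsic x→y→z; the order and centre are conventions
   (they are not uniquely determined by the task), fixed and documented
   so components are comparable across runs of this implementation, and
   `recompose_components()` rebuilds the exact transform.
3. **MAD after superimposition** — form difference independent of
   position.

A zero-step family is the built-in null: the same threshold seven times
must give exactly zero MAD and zero movement, and does.

## The phantom generator

Real scans cannot ship with the package, so every stage is validated on
synthetic phantoms (`phantom_spec()`, `generate_phantom()`) built from an
analytic geometry with known ground truth:

* **Geometry.** A solid sphere, or a hemispherical shell (the bowl of the
  anterior cranial fossa) between two concentric surfaces, kept on the
  upper side. Radii may be a length-3 vector: the presets use an
  ellipsoidal shell with semi-axes (12, 10, 8) mm — real anatomy has no
  rotational symmetry, and a symmetric phantom would make rotation about
  its axis unidentifiable for ICP, so the registration checks would be
  ill-posed.
* **Partial volume** is modelled as a Gaussian blur (`edge_sigma`, mm) of
  the binary geometry scaled to `[intensity_soft, intensity_bone]`
  (defaults 300 and 700 on the 0–1000 scale, consistent with overlapping
  soft/bone ranges in rescaled CBCT data: the true boundary intensity is
  500).
* **CBCT grayscale inhomogeneity** is a smooth multiplicative bias field:
  white noise blurred at a 30 mm length-scale and max-normalised, so the
  field is strictly positive and exactly bounded in `[1 - a, 1 + a]`.
  This emulates, with a single knob, the position dependence of CBCT
  voxel values.
* **Noise** is additive Gaussian. All randomness flows from one integer
  seed; identical spec + seed gives a bit-identical volume.

The acquisition presets (`phantom_preset()`) emulate the three image
classes studied — high-quality CT (0.5 mm voxels), regular CBCT (0.3 mm)
and low-quality CBCT (0.3 mm):

| preset | spacing (mm) | edge_sigma (mm) | noise_sd | bias a |
|---|---|---|---|---|
| `ct` | 0.5 | 0.75 | 10 | 0 |
| `cbct_regular` | 0.3 | 0.45 | 25 | 0.05 |
| `cbct_low` | 0.3 | 0.45 | 40 | 0.10 |

Noise and bias magnitudes are not published quantities for the machines
involved; they were fixed once at physically plausible values
(contrast-to-noise of roughly 40/16/10 for the three classes) and are
documented here rather than calibrated to any particular machine. The
partial-volume width scales with voxel size (1.5 × spacing), which is the
mechanism that makes the CT-like preset *more* threshold-sensitive: the
spatial displacement of an isosurface per unit of threshold change is
inversely proportional to the edge gradient, so a wider edge moves
further for the same offset. With the bias field on, part of the CBCT
surface discrepancy is a smooth warp that a rigid motion cannot remove,
so ICP recovers a smaller share of the CBCT effect than of the CT one —
the qualitative contrast the phantom study reproduces.

What the phantoms deliberately do not model: beam hardening, streaks,
metal artifacts, realistic skull anatomy, projection-domain physics.
Passing phantom tests therefore validates the estimators and the
pipeline mechanics, not performance on any particular clinical dataset.

## Statistics

`perm_mancova()` is a distance-based (PERMANOVA-style) multivariate
analysis on Euclidean distances computed from the raw responses — the
Gower-centred partitioning that, in Euclidean geometry, reduces to
classical sums of squares, so in the univariate single-factor limit the
pseudo-F equals the classical ANOVA F exactly. Each term is tested
conditionally on all the others (partial SS; the covariate is listed
first for presentation, but conditional tests do not depend on order),
with the full-model residual mean square as denominator. P-values come
from **permutation of residuals under the reduced model**
(Freedman–Lane): residuals of the design without the tested term are
row-permuted, added back to the reduced-model fit, and the pseudo-F
recomputed; with the default 999 permutations the smallest attainable
p is exactly `1/(999+1) = 0.001`. Choices worth knowing:

* Mixed/random-effects expected-mean-square denominators are not
  implemented; every term is tested against the residual, and the scheme
  is recorded verbatim in the fitted object so results are auditable.
* No Monte Carlo asymptotic fallback for designs with few unique
  permutations; the object reports the count and warns below 100.
* Responses with zero total variation return `pseudo_F = NA`, `p = 1`
  explicitly.
* Aliased terms (zero effective df) are an error naming the term.

Pairwise follow-ups use `friedman_test()` (complete blocks, k ≥ 3,
tie-corrected; the no-variation case returns statistic 0, p = 1),
`wilcoxon_signed_rank()` (zeros dropped and counted; exact p up to 25
non-zero pairs, normal approximation with continuity correction beyond),
and `bonferroni_adjust()` (`min(1, m p)`).

## Numerical choices and degenerate inputs

* Isosurface extraction classifies a sample as "inside" iff
  `value < iso`, so vertices are well-defined even when the level set
  passes exactly through grid samples; zero-area faces are removed.
* An iso value outside the volume's range, an empty crop, an empty label
  class, a degenerate intensity window, and non-uniform DICOM slice
  spacing (beyond 1%) are all errors with specific messages.
* ICP with an all-planar reference warns that in-plane translation is
  unidentifiable; gimbal lock in the Euler decomposition (|ry| = 90°) is
  resolved by the documented convention rz = 0, with a warning.
* Ties in closest-point queries (a point equidistant to adjacent
  triangles) resolve to the same distance bit-for-bit regardless of
  traversal order; only the reported witness point may differ in the
  last ulp.

## Problem sizes

The shipped tests and the acceptance script run the full pipeline on
phantom grids of roughly 60³–115³ voxels (meshes of 5,000–60,000
vertices), ten phantoms per acquisition mode for the study-level checks,
and 500 replicate datasets of n = 40 for the permutation-test
calibration. These sizes were chosen to make the complete analysis
reproducible on a single CPU in minutes while keeping every estimate
well inside its tolerance.

## Known limitations

* Operator-dependent steps of the clinical workflow (visual threshold
  choice, manual voxel labelling of real anatomy) are replaced by
  phantom ground truth; the package quantifies threshold sensitivity,
  not operator behaviour.
* Movement components are convention-dependent (Euler order, rotation
  centre); compare them only within this implementation.
* The bias field is a generic smooth inhomogeneity, not a
  machine-specific artifact model, and preset noise levels are plausible
  stand-ins, not calibrated to specific hardware.
* MAD is the only distance summary; Hausdorff or percentile metrics are
  straightforward extensions but are not provided.
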