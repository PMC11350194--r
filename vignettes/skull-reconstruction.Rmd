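---
title: "Skull surface reconstruction by point-cloud completion: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Skull surface reconstruction by point-cloud completion: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Maxillofacial surgery planning frequently requires a *eumorphic* (well-formed)
model of a patient's skull where part of it is missing — congenitally,
after trauma, or after resection. `skullrec` treats this as a *shape
completion* problem on point clouds: from a triangle mesh segmented out of a
CT scan, extract a clean external-surface point cloud, remove (or accept from
the surgeon) a defective region, let a completion backend predict the missing
geometry, and mesh the result so it can seed implant design. The package
implements the full benchmark pipeline around the completion step — the
completion network itself is deliberately pluggable, since training one is a
GPU problem that lives outside this package. A classical mirroring baseline
and a stored-prediction adapter are included.

All coordinates are millimetres in a Natural-Head-Position frame: z up,
y anterior, x left-to-right, so the sagittal plane is x = 0.

## Pipeline stages and their assumptions

1. **Alignment** (`kabsch_align`, `icp_refine`). Three anatomical landmarks —
   the left and right frontozygomatic sutures and the basion — define a
   least-squares rigid fit (cross-covariance SVD with a determinant guard
   against reflections), refined by point-to-point ICP. ICP runs on sampled
   clouds rather than meshes, with the full correspondence set and no
   rejection gate by default (clouds are pre-cleaned); a `max_dist` gate is
   available. The solver and ICP variant are the package's choices; the RMS
   residual is non-increasing by construction of the least-squares step.
2. **External-surface extraction** (`extract_external_surface`). CT-segmented
   skull meshes carry large interior structures that are clinically
   irrelevant for implant shaping. Ten orthographic snapshots — eight
   azimuthal at 45° steps around the vertical axis plus a parietal and a
   basilar view — are rendered with a software z-buffer; every foreground
   pixel is back-projected into the world frame, so only depth-buffer-visible
   (external) surface survives. Cameras are orthographic to make
   back-projection exactly invertible and framing scale-free, and the eight
   azimuthal views sit at zero elevation. The merged cloud is Poisson-disk
   simplified to 40,000 points.
3. **Defect injection** (`sample_defect`, `apply_defect`). Virtual defects
   are axis-aligned cuboids with a square base in the axial plane, side and
   height uniform in [30, 100] mm, centred on a cloud point drawn from a
   quality-score-dependent region. Containment is boundary-inclusive so that
   removal and later region retention are exact complements. Draws that would
   remove fewer than 100 points are rejected (up to 20 redraws) to avoid
   degenerate defects in empty space.
4. **Normalization** (`normalize_pair`). Both clouds are centred on the
   *partial* cloud's centroid (the only centroid available at deployment)
   and divided by a fixed scale m = 155 mm — the maximum per-cloud centred
   norm over the reference training data, recomputable for synthetic sets via
   `compute_training_scale`. A fixed m keeps corresponding anatomy at the
   same normalized scale whatever the defect size; per-cloud max-norm
   (ShapeNet-style) scaling does not, which is exactly what the
   defect-size-stability check in the test suite demonstrates. Clouds larger
   than m warn rather than fail.
5. **Completion and merge** (`complete`, `extract_defect_region`,
   `merge_completion`). Backends operate in normalized space with declared
   input/output sizes. Only completed points inside the (undilated) defect
   cuboid are retained and concatenated with the partial input; the merged
   cloud carries trustworthy normals — inherited from the source mesh at
   extraction time — only on the partial part, and all-NA normal rows flag
   the reconstructed region for estimation.
6. **Meshing** (`reconstruct_surface`). PCA normals for the flagged points,
   consistent tangent-plane orientation for the whole set, Poisson surface
   reconstruction, and a boundary-edge (hole) count reported on the result.
7. **Evaluation** (`evaluate_reconstruction`). Accuracy, completeness,
   Chamfer distance, Earth Mover's distance and F-score at τ = 3 mm, always
   after de-normalization and restricted to the defect region. Distances are
   plain (unsquared) Euclidean.

## The mirror baseline and its sagittal plane

`backend_mirror` reflects the partial cloud and keeps whatever falls in the
defect. One subtlety: normalization centres on the partial centroid, which a
unilateral defect pulls away from the midline, so "normalized x = 0" is *not*
the sagittal plane. The backend therefore mirrors about the aligned frame's
x = 0 mapped into normalized coordinates (`-centroid_x / m`). Mirroring is
only meaningful for unilateral damage; a defect crossing the sagittal plane
leaves a hole and degraded completeness, which the pipeline reports rather
than hides.

## Poisson reconstruction: a spectral uniform-grid variant

No reconstruction library is assumed; the package solves the Poisson
indicator problem directly:

* oriented unit normals are splatted with trilinear weights onto a cubic
  `2^depth` grid whose central 60% contains the cloud;
* the vector field is smoothed by a Gaussian whose width is
  `max(1.5 h, median nearest-neighbour spacing)` — wide enough to bridge
  sample gaps, narrow enough to keep detail;
* the equation ∇²χ = ∇·V is solved in Fourier space with *matched discrete
  operators* (central-difference divergence `i sin(2πk/G)/h` and the discrete
  Laplacian eigenvalues `(2 cos(2πk/G) − 2)/h²`), making the solve an exact
  discrete solution rather than a spectral approximation; the zero-frequency
  mode is fixed to zero;
* the iso-level is the mean interpolated χ at the samples, and the level set
  is extracted with **marching tetrahedra** on the Freudenthal (6-tet)
  decomposition. Unlike classic marching cubes this has no ambiguous cases,
  so the extracted surface is crack-free and watertight by construction;
  vertices are welded exactly via grid-edge keys.
* faces whose vertices all fall below a density threshold — 0.25 × the 0.01
  quantile of the smoothed sample density — are trimmed, and disconnected
  components below 1% of the largest are dropped as trapped "bubble"
  artifacts.

`poisson_depth` defaults to 7 (a 128³ grid). On a ~250 mm skull that is a
1–2 mm voxel, comfortably below the 3 mm evaluation threshold, and the
spectral solve stays small (a handful of 128³ FFTs). Higher depths are
supported up to 12; memory grows as 8× per level, which is why the uniform
grid is run at a lower exponent than octree implementations typically quote.
On a 10k-point sphere of radius 50 mm this reconstruction recovers the
analytic area to well under 1% with zero boundary edges and Euler
characteristic 2 (see the test suite).

The known failure mode — inconsistently oriented normals in the reconstructed
region — reproduces faithfully: flipped defect-region normals cancel the
divergence source locally, the surface wanders into low-density space, the
density trim removes it, and the result is a positive boundary-edge count
that `reconstruct_surface` reports.

## The synthetic fixture: what it does and does not emulate

`make_synthetic_skull` builds a two-shell ellipsoid: a closed outer shell
(semi-axes 90/110/80 mm, the scale of an adult skull) and a disjoint interior
shell at 60% scale standing in for internal bone structure, plus an optional
symmetric lower-anterior protrusion standing in for the maxilla/mandible.
This exercises everything the pipeline assumes about real data — internal
points to suppress, approximate left–right symmetry for the mirror baseline,
a lower anterior region for the quality-score placement rules, and
CT-scale vertex counts (subdivision level 6 gives ~294k vertices, inside the
250k–400k range typical of segmented skulls). It does **not** emulate real
cranial geometry: no orbits, no zygomatic arches, no surface texture, no
segmentation noise, perfect rather than approximate symmetry. Green tests on
the fixture therefore validate the *pipeline machinery* — visibility logic,
partitioning, normalization algebra, meshing topology, metric computation —
not clinical reconstruction quality, which depends on the completion backend
and real anatomy.

Fixture generation is deterministic; the region presets (fractions of the
cloud bounding box: splanchnocranium z ∈ [0, 0.45], y ∈ [0.5, 1];
maxilla/mandible z ∈ [0, 0.30], y ∈ [0.5, 1]; orbit z ∈ [0.40, 0.60],
y ∈ [0.6, 1]) are package conventions chosen to match the anatomy they name
on this frame, and are configurable.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `image_size` | 1024 | px | ~0.33 mm pixel footprint on a 250 mm skull, an order below τ; 256–384 px reproduces the coarser snapshot density of typical CT-derived benchmarks (merged clouds of 100–300k points) |
| `target_points` | 40000 | points | the simplified cloud size the pipeline standardizes on |
| `m` | 155 | mm | fixed normalization scale (max training-cloud scale); recompute for new datasets |
| defect size range | [30, 100] | mm | clinically plausible resection scale (3–10 cm) |
| `tau` | 3 | mm | F-score threshold |
| `k_c` | 30 | neighbours | PCA normal estimation support; large enough to be stable on 40k-point skull clouds at ~1.6 mm spacing |
| `k_tg` | 10 | neighbours | orientation graph degree; keeps the MST local |
| `poisson_depth` | 7 | – | 128³ grid, 1–2 mm voxels on a skull (see above) |
| `trim_quantile` | 0.01 | – | density quantile anchoring the bubble trim |
| EMD cap | 2048 | points | exact Hungarian assignment stays tractable; downsampling is seeded uniform and recorded in the report |

## Numerical conventions

* STL welds per-facet vertices at 1e-6 mm; PLY is written in double precision
  so read/write round trips are exact to well below 1e-6 mm.
* Poisson-disk simplification is greedy dart throwing in a seeded random
  order with the radius bisected until the accepted count is within 2% of
  target; the output is a subset of the input with a guaranteed minimum
  pairwise distance.
* Farthest-point sampling starts at `seed mod n`; uniform resampling is
  seeded. Every stochastic step in the pipeline takes an explicit seed, and a
  full `run_pipeline` is bit-reproducible given its configuration.
* Degenerate inputs fail loudly at the type level (non-finite coordinates,
  degenerate faces, collinear landmarks, reflections posing as rotations),
  with one deliberate exception: an empty reconstructed region yields an
  infinite-accuracy, zero-F-score sentinel report so batch tables stay
  rectangular.
* Orientation propagation resolves the global sign per connected component by
  majority vote on centroid-outwardness; disconnected orientation graphs are
  oriented per component with a warning.

## Problem sizes used in the checks

The shipped test suite runs the geometry at the scales the pipeline is
specified for where that is cheap (extraction at 1024² on the ~294k-vertex
fixture, 40k-point clouds, τ = 3 mm) and at reduced sizes where a smaller
instance checks the same property (e.g. Poisson meshing on 10k-point spheres,
EMD oracles on ≤7-point clouds where exhaustive enumeration is exact). The
`scripts/acceptance.R` script re-runs the headline computations from scratch
at the standard sizes and writes the measured quantities as JSON.

## Known limitations

* Completion quality is entirely backend-dependent; the built-in mirror
  baseline fails by design on bilateral defects.
* Landmarks are user-supplied; there is no automatic landmark detection, and
  DICOM/CT segmentation is out of scope (inputs are meshes).
* The uniform-grid Poisson solve trades the adaptivity of octree
  implementations for simplicity and exact reproducibility; very fine
  detail below the voxel size is smoothed.
* Quality scores are metadata supplied with a dataset, not estimated from
  the scans.
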