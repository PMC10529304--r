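---
title: "Methods: CT-based nodal segmentation and PET semi-quantification"
author: "nodeseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CT-based nodal segmentation and PET semi-quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Intraoperative specimen PET/CT imagers produce paired high-resolution
volumes of resected surgical specimens — CT at 0.1 mm voxels, PET at
0.4 mm — within minutes of excision. Reading tracer uptake out of a
lymph-nodal specimen quantitatively requires a volumetric segmentation of
the nodal structures, and manual slice-by-slice contouring costs on the
order of 15 minutes per node: far too slow for the operating room.
`nodeseg` automates that segmentation from the CT channel alone and then
applies the resulting masks to the PET channel to compute per-node SUVmax
and target-to-background ratios (TBR).

The setting is deliberately simple compared to whole-body imaging: a
resected specimen in a cylindrical container holds essentially four
materials, well separated in CT attenuation — air, the plastic container,
fatty tissue, and soft tissue (nodes, plus attached vessels and fibrotic
strands). The method exploits exactly that separation.

## The segmentation model

The pipeline is a fixed sequence of interpretable stages:

1. **1-D k-means clustering** (`fit_kmeans_1d`, `assign_clusters`): Lloyd's
   algorithm with k = 3 on the scalar attenuation values splits voxels into
   density-ordered clusters — air, fat, and node/soft tissue. Centroids are
   reported in ascending order and mapped to tissue roles by rank, since
   the three tissue classes are density-ordered by physics. Attenuation is
   treated as an *ordinal* scale throughout; no Hounsfield calibration is
   assumed, because only the ordering matters to a clustering in one
   dimension.
2. **Node-cluster extraction** (`extract_node_mask`): the fat cluster is
   assigned to background, leaving a binary mask of the highest-density
   cluster. This mask still contains the container wall, vessels, fibrous
   bridges, and speckle from noise.
3. **Geometric case removal** (`remove_case`): voxels at radial distance
   ≥ (radius − margin) from the container's cylinder axis are cleared.
   The geometry can be supplied or estimated from the non-air voxels
   (`estimate_case_geometry`); the estimator takes the bounding-box centre
   and maximal radial extent of the non-air projection, is best-effort by
   design, and is always overridable in the configuration.
4. **Erosion** (`erode`): removes speckle and detaches thin, wrongly
   connected structures (vessels, fibrosis) from the nodes.
5. **Hole-filling** (`fill_holes`): background cavities not connected to
   the volume border are filled. This recovers the lymph-node hilum, whose
   fat-like density excludes it from the node cluster. Filling is done in
   3-D by default — a hilum is a 3-D cavity — with a per-slice variant
   (`fill_2d`) available as a configuration switch.
6. **2-D small-feature removal** (`filter_small_2d`): per axial slice,
   connected components below `min_pixels_2d` pixels are discarded.
7. **Dilation** (`dilate`): compensates the erosion (equal radii by
   default) and re-joins broken parts of the same structure.
8. **3-D small-feature removal** (`filter_small_3d`): components below
   `min_voxels_3d` voxels are discarded.
9. **Component labelling** (`label_components`): the surviving components
   are labelled 1..C deterministically, ordered by each component's
   minimal column-major voxel index.

`segment_nodes` runs all stages, records a per-stage trace of foreground
voxel and component counts, and treats an empty result as a valid outcome
("no nodes found"), not an error.

### Parameters and defaults

| parameter | default | units | rationale |
|---|---|---|---|
| `k` | 3 | clusters | air / fat / node-plus-vessel |
| `n_init` | 5 | restarts | deterministic k-means++ with best-of-restarts; in this 1-D, well-separated setting initialization does not change the solution, but a fixed contract is needed for reproducibility |
| `subsample` | all voxels | voxels | optional fit-time cap (e.g. 2×10⁶) for very large volumes; assignment always covers every voxel |
| `erosion_radius`, `dilation_radius` | 2 | voxels | 0.2 mm at CT spacing: thinner than any node, thicker than vessel bridges; equal radii so dilation compensates erosion |
| `element` | ball | — | isotropic; a radius-1 ball is the 6-neighbourhood |
| `min_pixels_2d` | 20 | pixels | 0.2 mm² at 0.1 mm spacing; well below a node cross-section |
| `min_voxels_3d` | 500 | voxels | 0.0005 mm³-scale; an order of magnitude below the smallest node of interest |
| `connectivity_2d` / `_3d` | 8 / 26 | — | standard full-neighbourhood defaults |
| `case_margin` | 0.5 | mm | strips the wall plus a safety band |

None of the morphological radii or size thresholds is dictated by the
method itself; all were chosen once on the synthetic phantom at 0.1 mm
spacing and are exposed in a fully-defaulted YAML configuration
(`read_pipeline_config`) so that every such choice is user-auditable.

### Tie-breaking and numerical conventions

* Voxel assignment ties (a value exactly half-way between two centroids)
  go to the lower-centroid cluster, both during fitting and assignment.
* k-means convergence: maximum centroid shift ≤ `tol` (default 1e-8) or
  `max_iter` (default 100). Fitting sorts the sample once and uses prefix
  sums, so each Lloyd iteration is a few binary searches.
* Resampling ties (a target centre exactly equidistant between two source
  centres) take the lower source index; the source field of view is the
  closed interval extending half a voxel beyond the outermost centres, and
  target voxels outside it become background.
* Component labels are assigned in order of first encounter in
  column-major scan order, making labelling platform-independent.
* Report rounding is half-away-from-zero (2 decimals for metrics, 1 for
  TBR); all stored values keep full precision.
* Degenerate metric quotients (0/0, e.g. precision with an empty
  prediction) are reported as absent (`NA`), never as 0.

## Geometry and I/O conventions

Volumes and masks are plain 3-D arrays with a physical grid: `spacing`
(mm per voxel) and `origin` (world-mm coordinate of the centre of the
first voxel); world = origin + index × spacing per axis. Files are
NIfTI-1 with an axis-aligned affine; rotated or sheared affines are
rejected loudly, because the specimen-imaging context gives no rotation
semantics and an axis-aligned contract keeps resampling exactly testable.
Masks are stored as 32-bit integers and files with fractional voxel
values are rejected as masks.

## PET semi-quantification

`resample_mask` moves the CT-grid mask to the PET grid (e.g.
1024×1024×512 @ 0.1 mm → 252×252×152 @ 0.4 mm) by separable
nearest-neighbour lookup; a label set never grows under resampling, and
this is asserted on every call. `suvmax` is the PET maximum over a
label's voxels; `tbr` divides it by a background SUVmax. The background
("non-target") region is not uniquely defined in this application, so two
strategies are offered and neither is claimed to be canonical: an
explicit user ROI, or (default) the specimen interior outside the node
mask dilated by a configurable margin (1 mm default), with the interior
taken as the positive-uptake support when no region is supplied.
`suv_scale` converts activity concentrations (Bq/mL) to body-weight SUV.
Decay correction is out of scope: volumes are assumed scanner-corrected.

## Evaluation

`evaluate` compares an automatic mask against a reference mask voxel-wise.
Reference labels act as classes; predicted components are first attributed
to the reference node with maximal overlap (`match_components`, ties to
the lower label). Per class, the five metrics — precision, recall, Dice,
Jaccard, accuracy — are computed from full-field-of-view confusion counts,
then aggregated three ways: macro (unweighted mean), weighted (reference-
voxel-weighted mean), micro (metrics of pooled counts). Predicted
components overlapping no reference node contribute their voxels once as
pooled false positives, so spurious detections cannot hide. True negatives
are counted over the whole volume including air; with nodes occupying
well under 1 % of the field of view this deliberately reproduces the
inflated "overall accuracy" that class imbalance produces — accuracy is
reported, but Dice/Jaccard are the honest summaries. Support is defined
as reference voxels per class (the union-based alternative changes the
weighted rows only in the third decimal on realistic masks).

## The synthetic phantom

No specimen scans are publicly deposited, so validation rests on a
parametric phantom (`phantom_spec`, `generate_phantom`) that emulates
what the method actually relies on:

* a cylindrical container (default inner radius 6.5 mm, wall 0.3 mm)
  filled with fat-density background, air outside;
* ellipsoidal nodes (default: three equal 1.5 mm-radius spheres, ≥ 2 mm
  apart, placed by bounded rejection sampling with a deterministic RNG
  stream per node index);
* optional low-density hila (ellipsoids at 35 % of the node's semi-axes,
  offset inside the node) and thin vessel bridges touching node surfaces;
* Gaussian CT noise (default SD 20 against a fat-node contrast of 140,
  i.e. 7 SDs — "easy" by construction);
* a paired PET volume on its own 0.4 mm grid: uniform background uptake
  (SUV 1.5) inside the container, a truncated-Gaussian radial uptake
  profile inside each node pinned to the configured peak (SUV 8.0) at the
  node centre, and clipped noise (±3 SD of 0.05) so that node SUVmax and
  the background ceiling are analytically known.

Default intensities are air −1000, hilum −300, fat −100, node +40,
container +100 in arbitrary attenuation units. The container is given a
soft-tissue-like intensity deliberately: plastic is close to soft tissue
in CT attenuation, so the wall joins the *node* cluster — which is
precisely why the pipeline removes it geometrically rather than by
density. (A much denser wall would claim a k-means cluster of its own and
change the method's premise.)

`perturb` generates one-dimension-at-a-time difficulty sweeps (noise SD,
fat-node contrast, node separation) for robustness studies; each swept
spec regenerates bit-identically under its seed.

### What the phantom does and does not show

The phantom captures the tissue-density ordering, the container, grid
asymmetry between CT and PET, hila, vessel bridges, and additive noise.
It does **not** capture irregular node shapes, heterogeneous intra-nodal
density, reconstruction artefacts, or partial-volume effects at tissue
interfaces. Passing phantom tests therefore demonstrates correctness of
the implementation under the stated model, not clinical performance: on
real specimens, recall is expected to degrade with structural
heterogeneity (the contrast-narrowing sweep reproduces that direction of
effect qualitatively).

## Problem sizes used in validation

Unit tests run on 96³ phantoms (two 0.9 mm nodes, container radius
3.8 mm) so the whole suite stays fast; the reference recovery checks and
the difficulty sweep use the full default 160³ phantom; the resampling
stress check exercises the full-scale 1024×1024×512 → 252×252×152 grid
pair. Clustering in the pipeline tests fits on a fixed-seed uniform
subsample (2–5×10⁵ voxels) and assigns to all voxels, which on this
easy 1-D problem changes centroids by well under one attenuation unit.

## Known limitations

* The case estimator assumes the container axis is grid-aligned.
* Clustering is per-volume; no information is shared across scans.
* k = 3 is structural: specimens with a fourth well-populated density
  class (e.g. calcifications) would need a larger k and a different
  role mapping.
* The evaluation reports voxel-overlap quality only; it says nothing
  about the *detection rate* of pathological nodes.
* SUVmean/SUVpeak/MTV/TLG and radiomic features are out of scope.
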