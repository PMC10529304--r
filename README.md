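# nodeseg

Automatic lymph-node segmentation and PET semi-quantification for
intraoperative specimen PET/CT images.

## The problem

Mobile specimen PET/CT imagers let surgeons image resected lymph-nodal
specimens in the operating room within minutes of excision: a CT volume at
0.1 mm voxels paired with a PET volume at 0.4 mm voxels. Quantifying
tracer uptake per node (SUVmax, target-to-background ratio) needs a
volumetric segmentation of the nodal structures, and manual contouring
takes ~15 minutes per node. `nodeseg` automates the segmentation from the
CT channel and applies the resulting masks to the PET channel.

The specimen context is anatomically simple — air, a plastic container,
fat, and soft tissue (nodes plus attached vessels/fibrosis), well
separated in CT attenuation — so an interpretable clustering model
suffices:

1. 1-D k-means (k = 3) on CT attenuation separates air / fat /
   node-and-vessel by density; the fat cluster is sent to background,
   leaving a binary node-cluster mask;
2. the container is removed by radial distance from its cylinder axis;
3. binary erosion detaches wrongly-connected vessels and removes speckle;
4. hole-filling recovers the low-density node hilum;
5. 2-D (per-slice) and, after a compensating dilation, 3-D small-feature
   filters discard noise components;
6. the surviving components are labelled deterministically.

The mask is then resampled onto the PET grid by nearest neighbour (no new
labels can appear) and per-node records are computed:

```
SUVmax(node) = max of PET SUV over the node's voxels
TBR          = SUVmax(node) / SUVmax(background, non-target region)
```

Against a reference mask, `evaluate()` reports per-node precision, recall,
Dice (`2TP/(2TP+FP+FN)`), Jaccard and accuracy, with micro / macro /
weighted averaging.

A parametric specimen phantom (container + fat background + ellipsoidal
nodes with optional hila and vessel bridges + paired PET with known peak
uptake) provides ground truth for end-to-end validation; no clinical data
ships with the package.

## Worked example

```r
library(nodeseg)

ph  <- generate_phantom(phantom_spec(seed = 0))   # ct, pet, truth, meta
res <- segment_nodes(ph$ct)                       # full pipeline
res$trace
#>          stage voxels components
#> 1 node_cluster 245409          5
#> 2 case_removed  41889          4
#> 3       eroded  19769          3
#> 4       filled  19868          3
#> 5  filtered_2d  19724          3
#> 6      dilated  39776          3
#> 7  filtered_3d  39776          3
#> 8     labelled  39776          3
```

The trace reads as the pipeline narrative: the raw node cluster (245k
voxels, 5 components) contains the container wall and noise; case removal
and erosion strip them (3 components = the 3 phantom nodes); filling adds
back ~100 interior voxels; dilation restores the eroded bulk.

```r
evaluate(res$mask, ph$truth)
#> Per-class (reference node) metrics:
#>  class support precision recall dice jaccard accuracy
#>      1   14127         1   0.94 0.97    0.94        1
#>      2   14125         1   0.94 0.97    0.94        1
#>      3   14143         1   0.94 0.97    0.94        1
#> Aggregates:
#>   average precision recall dice jaccard accuracy
#>     micro         1   0.94 0.97    0.94        1
#>     macro         1   0.94 0.97    0.94        1
#>  weighted         1   0.94 0.97    0.94        1

quantify(ph$pet, res$mask)   # resamples the CT mask to the PET grid
#>   label voxels suvmax background_suvmax      tbr
#> 1     1    205      8              1.65 4.848485
#> 2     2    207      8              1.65 4.848485
#> 3     3    203      8              1.65 4.848485
```

SUVmax equals the phantom's configured peak (8.0) exactly, and the
background ceiling (1.5 + 3 clipped noise SDs = 1.65) bounds the TBR —
the phantom is built so these are analytic.

A command-line interface wraps the same functions:

```sh
exec/nodeseg demo --out-dir out --seed 0
exec/nodeseg segment --ct ct.nii.gz --config cfg.yaml --out mask.nii.gz
exec/nodeseg quantify --pet pet.nii.gz --mask mask.nii.gz --out quant.csv
```

See `vignettes/nodeseg-methods.Rmd` for the model, parameter rationale,
and the phantom's scope and limitations.

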