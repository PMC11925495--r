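# BinToCell

Recovering single-cell expression profiles from sub-cellular spatial
transcriptomics bins.

## The science

Sequencing-based platforms such as Visium HD capture transcripts on a
continuous lattice of 2×2 µm square **bins**. The lattice is agnostic to
tissue structure: one cell covers tens of bins, and wherever cells touch, a
bin can straddle two or more of them. To get the cells × genes matrix that
single-cell methods expect, each bin's counts must be assigned to cells —
the **bin-to-cell assignment** problem.

BinToCell represents bins (half-open squares) and segmented cell outlines
(simple polygons) exactly, computes every positive bin–cell intersection
area with an exact polygon clipper (contractually identical to a
brute-force all-pairs join), removes orphan bins that touch no cell, and
distributes counts under one of four strategies:

| strategy | shared bins are… | character |
|---|---|---|
| `naive` | discarded | highest precision, lowest recall |
| `weight_by_area` | split by intersection area | geometric default |
| `weight_by_gene` | split per gene by unique-bin expression profiles | best F1 when unique bins are informative |
| `weight_by_cluster` | split by expression-cluster mean profiles | borrows strength across similar cells |

All weighted strategies conserve transcript mass over overlapping bins; the
naive total equals the unique-bin total exactly. The package also provides
marker-score cell-type annotation, nucleus-outline expansion, label-mask
ingestion, a synthetic ground-truth tissue generator with calibrated
`"dense"` (~25% shared bins) and `"sparse"` (~0%) benchmark presets,
transcript-level precision/recall/F1 evaluation, and a deterministic
end-to-end pipeline.

The package uses Bioconductor-style S4 classes (`BinGrid`, `CellOutlines`,
`OverlapTable`, `CellByGeneMatrix`, `CellAnnotation`) with validity checks
and accessor generics; `asSingleCellExperiment()` bridges into the
Bioconductor ecosystem.

## Worked example

```r
library(BinToCell)
options(BinToCell.log = "warn")

cfg <- tissueSimConfig("dense", seed = 1)   # 220-cell packed tissue
ds  <- makeDataset(cfg)                     # ground truth + binned observation
ds@grid
#> BinGrid: 7225 bins (2 um) on a 85 x 85 lattice, 60 genes, 38642 counts
ds@truth@cells
#> CellOutlines: 220 cells, area 49.6-131.2 um^2 (median 84.9)

overlaps <- spatialJoin(ds@grid, ds@truth@cells)
overlapStatistics(overlaps, ds@grid)$shared_fraction
#> [1] 0.2447917

grid  <- filterOrphanBins(ds@grid, overlaps)
truth <- trueCellMatrix(ds@truth)
for (st in c("naive", "weight_by_area", "weight_by_gene", "weight_by_cluster")) {
  m   <- assignBins(grid, overlaps, ds@truth@cells, strategy = st)
  met <- transcriptAssignmentMetrics(m, truth)
  cat(sprintf("%-18s precision %.3f  recall %.3f  F1 %.3f\n",
              st, met$precision, met$recall, met$f1))
}
#> naive              precision 0.966  recall 0.720  F1 0.825
#> weight_by_area     precision 0.890  recall 0.929  F1 0.909
#> weight_by_gene     precision 0.919  recall 0.959  F1 0.938
#> weight_by_cluster  precision 0.865  recall 0.902  F1 0.883
```

The trade-off is the package's central claim: discarding shared bins buys
precision at a steep recall cost, while weighted splitting recovers nearly
all transcript mass with a modest precision penalty.

Annotation against the generator's known marker programs:

```r
m   <- assignBins(grid, overlaps, ds@truth@cells, strategy = "weight_by_gene")
ann <- scoreCellTypes(m, trueMarkerSet(cfg))
ann
#> CellAnnotation: 220 cells, 6 scored types
#>   labels: type1(49) type2(45) type5(37) type3(32) type6(31) type4(26)
annotationMetrics(ann, ds@truth@cellTypes[cellIDs(m)])$accuracy
#> [1] 1
```

## Command line and pipeline

`inst/cli/hdassign.R` is a thin front end:

```sh
Rscript inst/cli/hdassign.R simulate --preset dense --seed 1 --out demo_ds
Rscript inst/cli/hdassign.R run --config config.yaml
Rscript inst/cli/hdassign.R evaluate --pred out/cell_by_gene --truth demo_ds
```

with a YAML config such as:

```yaml
input:
  counts_dir: demo_ds/bins
  outlines: demo_ds/cells.geojson
assignment:
  strategy: weight_by_area
output:
  dir: out
seed: 7
```

`runPipeline()` validates the config strictly (unknown keys are errors),
executes read → join → filter → assign → (annotate) → write, checks
transcript-mass conservation, and writes a JSON manifest with stage
timings, counts and metrics. Identical config and seed give byte-identical
outputs.

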