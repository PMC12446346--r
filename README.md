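# stromaSpatial

Quantifying the spatial distribution of cell markers relative to a modeled
stromal border in multiplexed immunofluorescence images of stroma-rich
tumors.

Dense, desmoplastic stroma — as in pancreatic ductal adenocarcinoma — acts
as a physical and signaling barrier, and many biological questions reduce
to: *how does a marker's per-cell intensity change with the cell's distance
to the stromal border?*  This package provides the full analysis chain for
that question, aimed at image analysts and cancer biologists working with
batches of multi-channel fluorescence images (DAPI / pan-cytokeratin /
fibronectin / marker of interest):

- **Stromal modeling** — Gaussian smoothing + intensity threshold on the
  fibronectin channel; the mask border is the spatial reference.
- **Signed distances** — exact Euclidean distance transform, negative
  inside the stroma, positive outside, in micrometres.
- **Cells** — classical nucleus segmentation (pluggable; external label
  masks import from TIFF/GeoJSON), 5 µm constrained radial expansion,
  per-compartment intensity features, nuclear-area QC filter.
- **Batch threshold calibration** — the core statistic: an expert
  threshold `t_i` chosen in one reference image is propagated to every
  other image by percentile preservation under fitted non-negative
  distributions (log-normal, Wald, Burr, beta, gamma; MLE fits,
  least-squares model selection against the histogram):

  `t_j = F_j⁻¹(F_i(t_i))`

- **Classification** — strict threshold labels, composite
  (marker⁺ ∧ cytokeratin⁺) cancer-cell restriction, confusion matrices
  with agreement percentages, external classifier-label import.
- **Spatial profiles** — 10 µm distance bins, bootstrap SEM per bin,
  bin-wise group differences with propagated error
  `SEM = sqrt(σ_a²/n_a + σ_b²/n_b)`.
- **Sensitivity analysis** — grid search over (σ, threshold), side-wise
  Pearson correlations `r(I, d)` inside/outside the stroma, exact paired
  Wilcoxon signed-rank tests, bootstrap summaries across images.
- **Phantom generator** — synthetic images and cell-table batches with
  known stromal geometry, distance-dependent log-normal marker signal and
  per-image multiplicative batch shifts, so the whole pipeline is testable
  without any external data.

## Worked example

Propagate a top-10% reference threshold across a 3-image phantom batch
with known multiplicative staining shifts (c = 1.0, 1.6, 0.7):

```r
library(stromaSpatial)

cfg   <- phantomConfig(nCells = 20000L, seed = 42L)
batch <- generateCellTableBatch(cfg, nImages = 3, scales = c(1.0, 1.6, 0.7))

tRef <- percentileThreshold(batch$tables$phantom_1$cell.marker.max, 0.10)
ths  <- propagateThresholds(batch$tables, "cell.marker.max", "phantom_1", tRef)
ths
#> ThresholdSet for 'cell.marker.max': reference 'phantom_1' at t=1.323e+04
#> phantom_1 phantom_2 phantom_3
#> 13230.477 21666.746  9310.681
```

The mapped thresholds track the ground truth `c · t_ref` =
(13230.5, 21168.8, 9261.3): images stained 1.6× brighter or 0.7× dimmer
get correspondingly scaled thresholds, so the *same fraction of cells* is
called positive everywhere — no per-image hand tuning.

The phantom's marker is brightest at the stromal border
(`g(d) = exp(-|d|/50)` on the log scale), and the spatial profile
recovers that:

```r
p <- spatialProfile(batch$tables$phantom_1, "cell.marker.max",
                    binWidthUm = 10, rangeUm = c(-100, 100),
                    nBoot = 200, seed = 1)
p
#> SpatialProfile of 'cell.marker.max' (all): 20 bins of 10 um on [-100, 100), 9927 cells
which.max(binMeans(p))          # peak bin is [0, 10) um — adjoining the border
correlationBySide(batch$tables$phantom_1, "cell.marker.max")
#>  inside outside
#>   0.383  -0.359
```

Intensity rises toward the border from both sides: positive correlation
with distance inside the stroma (d < 0), negative outside — the signature
of border enrichment.

The same chain runs end-to-end on simulated images (segmentation →
stroma → calibration → classification → profiles → sensitivity) with one
call, or from the shell via the bundled CLI:

```r
runPipeline(defaultRunConfig(), "out/")
```

```sh
Rscript inst/cli/stroma-spatial run-all --config run.yaml --out out/
```

Every output directory contains the resolved `config.yaml` and a log;
rerunning with the same seed reproduces every output byte-for-byte.

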