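---
title: "Methods: spatial marker distributions relative to a modeled stromal border"
author: "stromaSpatial"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial marker distributions relative to a modeled stromal border}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stromaSpatial)
```

## The problem

Stroma-rich tumors such as pancreatic ductal adenocarcinoma are dominated
by a dense extracellular-matrix compartment that shapes drug penetration,
mechanosensing and proliferation.  A recurring analysis task in multiplexed
immunofluorescence imaging of such tissue is: *how does a marker's per-cell
intensity vary with a cell's distance to the stromal border?*  Answering it
at batch scale requires four ingredients, each of which this package
implements and tests on synthetic phantoms:

1. a reproducible model of the stromal region and its border, built from a
   matrix-protein channel (fibronectin);
2. a signed distance from every cell to that border;
3. per-cell intensity features from segmented, compartmentalised cells; and
4. classification thresholds that remain comparable across images whose
   staining intensity drifts — the batch-calibration problem.

## Stromal model and the signed distance convention

The stroma is modeled as `Gaussian(channel, sigma) > threshold`.  Both
parameters are scientific knobs, not nuisance constants: `sigma` (pixels;
accepted in micrometres via `sigmaUnits = "um"`) trades edge fidelity
against noise, and `threshold` encodes the biologist's judgement of where
matrix staining becomes "stromal".  Because of that, the package ships a
sensitivity module (`runSensitivityGrid`) that re-derives every downstream
statistic over a grid of both parameters rather than trusting one setting.

The signed distance field is the exact Euclidean distance transform to
opposite-phase *pixel centres*: outside pixels carry `+EDT` to the nearest
stromal pixel, inside pixels `-EDT` to the nearest non-stromal pixel,
scaled to micrometres.  Two consequences of this convention are worth
stating because they differ from a "distance to the border line"
convention:

* there is no zero level — the innermost ring of stromal pixels sits at
  `-1` px and the adjacent outside pixels at `+1` px, so the field jumps by
  2 px across the border while being 1-Lipschitz elsewhere;
* a cell whose centroid lies on a border pixel reports a distance within
  one pixel of zero, which is far below the 10 µm bin width used
  downstream.

The transform is verified in the test suite against an O(N²) brute-force
scan over all opposite-phase pixels, exactly, on dozens of random masks.
Cells sample the field at the pixel containing their nuclear centroid; no
interpolation, since profiles are binned at 10 µm — roughly one cell
diameter and an order of magnitude coarser than a pixel.  Cells with
`d = 0` count as *outside* everywhere (bins are half-open `[a, b)` aligned
at 0, and the side split for correlations uses `d >= 0`), one convention
applied uniformly.

## Cells: segmentation, expansion, features, filtering

`segmentNuclei` is a deliberately classical segmenter — blur, Otsu (or
fixed) threshold, hole filling, distance-transform watershed, minimum-area
cleanup.  Neural segmenters outperform it on real tissue; the package
therefore treats segmentation as pluggable and accepts external label
masks (integer TIFF or GeoJSON polygons) via `importLabels`.  The phantom
generator guarantees non-touching nuclei, so on phantoms the classical
segmenter recovers every cell and the rest of the pipeline is testable
independently of segmentation quality.

`expandCells` approximates whole-cell boundaries by radial expansion of
each nucleus by 5 µm (the radius is a parameter; 5 µm is the conventional
cytoplasmic expansion for tissue sections).  Where expansions would
collide, each contested pixel goes to the nucleus whose pixel set is
nearest in exact Euclidean distance, ties to the lower label — a
deterministic, non-overlapping partition verified against a brute-force
nearest-nucleus scan.  Compartments then partition each cell exactly:
`cell = nucleus ∪ cytoplasm`, disjoint.

`extractFeatures` computes mean, median, min, max and standard deviation
per cell × channel × compartment, plus the nuclear centroid and area in
micrometre units (pixel `(1,1)` spans `[0, pixelSize)²`, origin top-left).
`filterByNuclearArea` removes, per image, nuclei strictly below the 5th or
strictly above the 99th percentile of nuclear area (linear-interpolation
percentiles; boundary values are kept) — a QC step against debris and
fused nuclei.  Per-image rather than pooled percentiles keep the filter
meaningful when images differ in magnification or cell size.

## Batch calibration by percentile mapping

The core statistical idea: an expert picks one threshold \(t_i\) in one
reference image; for any other image \(j\) the equivalent threshold is the
value at the same cumulative probability of that image's fitted intensity
distribution,
\[ t_j = F_j^{-1}\!\big(F_i(t_i)\big). \]

`fitDistribution` fits a pool of non-negative families — log-normal, Wald
(inverse Gaussian), Burr XII, beta (location/scale-extended to the data
range) and gamma — to each image's per-cell feature values.  Parameters
are estimated by maximum likelihood (closed forms for log-normal and Wald,
`MASS::fitdistr` for gamma, direct likelihood optimisation for Burr and
beta); the *selection* among families minimises the sum of squared
differences between the fitted density and the density-normalised
histogram at bin centres.  MLE-then-SSE-selection is numerically stable
(least-squares optimisation over parameters of heavy-tailed densities is
not) while keeping the least-squares criterion where it matters: choosing
the family.  The histogram uses `nBins = 200` equal-width bins by default
and is density-normalised so counts and densities are commensurable; the
bin count is exposed because no canonical value exists.  Fitting uses raw,
unclipped values — outlier clipping at the 1st/99th percentiles is a
visualisation device only, and clipping before fitting would bias the tail
that thresholds live in.

Why this works under batch drift: if image \(j\) equals image \(i\) with
every intensity multiplied by \(c\) (the dominant mode of staining
variability), then \(F_j(x) = F_i(x/c)\) and the mapped threshold is
exactly \(c\,t_i\) — the calibration is equivariant under the very
transformation it is meant to absorb.  The phantom exploits this: its
batch generator applies known multiplicative scales, so "mapped threshold
= scale × reference threshold" is a testable identity (recovered to well
under 2% relative error at 50,000 cells per image in the acceptance
suite).

Numerical contracts: every family's quantile function inverts its CDF to
machine precision (Wald uses bracketed root-finding polished by Newton
steps), and mapping round-trips `src → dst → src` are tested to below
1e-6 relative error across all family pairs.  Thresholds at CDF 0 or 1
are refused as unmappable.  `percentileThreshold` provides the direct
top-N% alternative: the empirical `1 - N/100` quantile (type 7), with the
strict rule *positive ⇔ value > threshold*, so ties are negative and on
continuous data exactly the expected count is labelled positive.

## Classification and agreement

`applyThresholdClassifier` stores open-vocabulary labels
(`label.<name>`), `compositePositive` encodes the cancer-cell restriction
(marker-positive AND cytokeratin-positive), and `confusionMatrix` reports
the cross-tabulation and agreement percentage (trace over total) between
any two labelings — the package's instrument for comparing threshold-based
labels against externally trained classifiers, whose predictions enter
through `importExternalLabels`.  Training such classifiers is out of
scope by design; their analytic use here is the agreement computation.

## Spatial statistics

`spatialProfile` bins cells by signed distance (default 10 µm bins on
[-100, 300] µm) and reports per-bin means with a bootstrap standard
error: cells within each bin are resampled with replacement (default 500
draws, seeded).  Cells — not images — are the resampling unit for
profiles; across-image uncertainty belongs to the sensitivity module,
which bootstraps image-level summaries instead.  Bins with one cell
report a mean but no SEM; empty bins report neither.

`profileDifference` subtracts two profiles on identical bins and
propagates the uncertainty as
\[ \mathrm{SEM} = \sqrt{\sigma_a^2/n_a + \sigma_b^2/n_b}, \]
the standard error of a difference of independent means; for equal groups
this reduces to \(\sqrt{2}\,\sigma/\sqrt{n}\), asserted to machine
precision in the tests.

`correlationBySide` computes the Pearson correlation between marker
intensity and signed distance separately for cells inside (`d < 0`) and
outside (`d >= 0`) the stroma.  Sides with fewer than two cells or zero
variance are flagged `NA` rather than propagated as spurious numbers.

## Sensitivity analysis

`runSensitivityGrid` rebuilds the mask, distances and side-wise
correlations for every (sigma, threshold) combination and every image.
Because both correlations of an image arise from the same image under the
same parameters, (inside, outside) values are paired; pairs are pooled
across grid points into one paired sample for the overall two-sided
Wilcoxon signed-rank test, and each grid point also reports per-side
medians and an across-image bootstrap (500 iterations) mean ± SE.
Degenerate grid points (empty or full masks) are flagged and skipped, not
fatal.

`pairedWilcoxon` drops zero differences, mid-ranks ties, and computes the
exact two-sided null by convolution over the doubled ranks for up to 25
non-zero pairs (ties included exactly); beyond that it uses the normal
approximation with tie correction and continuity correction, and labels
which method produced the p-value.  All-positive differences at n pairs
give the extreme \(p = 2/2^n\); full enumeration verifies the
distribution for every n ≤ 12 in the tests.

## The phantom: what it emulates, and what it does not

`phantomConfig()` defaults define the synthetic study conditions:

* 512 × 512 px at 1.286 µm/px — four times the 0.3215 µm/px of a typical
  20× whole-slide scan, chosen so ~300 non-touching cells and a 5 µm
  expansion stay resolvable at desk scale;
* a vertical stromal band covering the middle third (annulus and
  smoothed-noise blob geometries are available), with the fibronectin
  channel rendered as the smoothed band plus Gaussian noise;
* nuclei as disks with radius ~ N(4, 0.5²) µm rendered into the DAPI
  channel; a 70% cytokeratin-high "cancer" subset;
* marker intensity per cell drawn log-normal on the 16-bit grey scale,
  `log-location = log(5000) + g(d)`, `sdlog = 0.5`, with the distance
  effect `g(d) = exp(-|d|/50)` peaked at the border — a multiplicative
  intensity effect, matching how log-normal fluorescence responds to
  biology;
* a per-image multiplicative batch scale `c`, the regime in which
  percentile mapping has the exact answer `c·t_ref`;
* ground-truth positivity at the 90th percentile of the baseline
  log-normal (a top-10% rule at `g = 0`), scaled by `c` per image.

Everything is seeded: the same configuration reproduces the same bytes.
The phantom intentionally omits tissue texture, optical blur and the
point-spread function, autofluorescence, segmentation-hostile nuclear
clumping, and 3-D structure.  Tests passing on phantoms therefore
demonstrate the *pipeline's* correctness — geometry, calibration,
statistics — not robustness to real-tissue segmentation failure modes,
which is precisely why external label masks and external classifier
labels are first-class imports.

## Numerical and convention choices collected

* Images are 16-bit integer grey levels (0–65535); TIFF round-trips are
  exact at that depth.  The TIFF writer emits baseline files without
  resolution tags, so pixel size travels in the run configuration.
* Coordinates are micrometres, origin top-left, x rightward, y downward;
  pixel `(1,1)` spans `[0, pixelSize)²`; centroids average pixel centres.
* Percentiles are type-7 (linear interpolation) everywhere.
* Positivity is strictly greater-than everywhere.
* Expansion ties break to the lower label id; the expansion radius in
  pixels is `round(radius/pixelSize)`.
* Mask polygons are traced along pixel edges, so GeoJSON export
  re-rasterises to the source mask exactly (even-odd rule at pixel
  centres); holes are interior rings.
* Cell tables are written with 17 significant digits so native-CSV round
  trips are bit-exact.
* Constant samples, empty masks, full masks, all-zero difference vectors
  and sub-100-cell images are refused or flagged with explicit messages
  rather than silently degraded.

## Problem sizes used by the automated checks

The test and acceptance suites run at sizes chosen to make the statistical
assertions sharp while staying desk-sized: 50,000 cells × 5 images for
threshold-recovery (2% tolerance), 20,000 cells × 100 replicates for
family selection (≥95% log-normal wins), 64 × 64 masks × 50 replicates
for exact distance-transform agreement, 20,000-cell profiles for peak
localisation, and the default 3-image × 300-cell phantom for the
end-to-end byte-determinism check.

## Known limitations

* Stromal delineation is intensity thresholding; texture- or
  learning-based segmentation is out of scope.
* The classical nucleus segmenter is a stand-in; use label-mask import
  for production segmentation.
* All distances are 2-D; sections are treated as planes.
* Calibration assumes a common distributional family per feature across
  the batch; images whose intensity distortion is not monotone (not a
  plain CDF shift) would violate the percentile-preservation premise.
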