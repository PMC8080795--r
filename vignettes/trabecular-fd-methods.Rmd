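---
title: "Methods: fractal dimension and radiomorphometrics of mandibular bone"
author: "trabeculaR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fractal dimension and radiomorphometrics of mandibular bone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trabeculaR)
```

## What the package computes

Dental panoramic radiographs carry two families of quantitative markers
of mandibular bone quality. The first is textural: the trabecular
(spongy) bone pattern, whose complexity is summarized by a box-counting
**fractal dimension (FD)** computed on a standardized 100 x 100-pixel
region of interest (ROI). Denser, more interconnected trabecular
networks give skeletons with higher FD; sparse or sclerotic patterns
give lower values. The second is geometric: the **mandibular cortical
width (MCW)**, the thickness of the inferior mandibular cortex measured
below the mental foramen, and the ordinal **mandibular cortical index
(MCI)**, Klemetti's C1/C2/C3 visual grading of endosteal erosion.
trabeculaR implements the FD pipeline, the MCW construction, MCI
tabulation, and the statistical battery used to compare two patient
groups, plus seeded synthetic generators that let every stage be tested
end to end without access to patient images.

## The fractal-dimension pipeline

`computeFD()` applies, in order:

1. **Crop** (`extractROI()`): an exact `size` x `size` tile (default
   100 px) at a 0-based origin. Out-of-bounds regions are errors, never
   clipped — the method depends on a fixed tile.
2. **Gaussian blur** (`gaussianBlur()`, sigma 35 px): estimates the
   large-scale brightness field (soft-tissue shadowing, exposure
   gradients). Separable convolution, kernel truncated at 4 sigma,
   mirrored borders, result re-quantized to 8 bits.
3. **Subtract + offset** (`subtractOffset()`): `original - blurred +
   128`, clamped to [0, 255]. The corrected image is centred on
   mid-gray; structure darker than its local background falls below
   128.
4. **Binarize** (`binarize()`, threshold 128): the dark phase —
   trabecular bone — becomes foreground. The threshold equals the
   offset because the subtraction step deliberately centres the
   histogram there; a fixed threshold keeps the chain deterministic.
5. **Open** (`erodeDilate()`): one erosion then one dilation with a
   3 x 3 square element removes binarization speckle. Outside the
   raster counts as background (plain set-theoretic morphology).
6. **Skeletonize** (`skeletonize()`): two-subiteration thinning
   (Zhang–Suen conditions) to 1-pixel-wide, 8-connected curves.
   Candidates found in parallel are deleted *sequentially*, re-checking
   the connectivity condition against the current raster before each
   deletion; this makes component preservation exact (naive parallel
   deletion annihilates isolated 2 x 2 blocks). Endpoints and isolated
   pixels are never removed.
7. **Box count** (`boxCount()`, widths 2, 3, 4, 6, 8, 12, 16, 32, 64):
   grids anchored at the tile's top-left corner, partial boxes at the
   right/bottom edges counted, occupied boxes regressed as ln(count) on
   ln(width) by ordinary least squares. FD is minus the slope; natural
   logs are stored (the slope is base-invariant).

Every grayscale stage re-quantizes to integers 0–255, mirroring 8-bit
processing in the imaging tools the protocol comes from; the chain
contains no randomness, so identical inputs give bit-identical results.

```{r fd-example}
img <- makeTrabecularTexture(syntheticSpec("fbm_texture", side = 120,
                                           hurst = 0.5, seed = 7))
res <- computeFD(img, roiSpec("ROI2", 10, 10, 100))
res
boxCountTable(res@boxcount)
```

### Numerical choices and degenerate inputs

* **Grid anchoring.** No offset optimization is performed: one grid per
  width, anchored at the tile origin, partial edge boxes included.
  Whether edge boxes at non-divisor widths (3, 6, 12 into 100) are
  counted changes counts by at most the edge row/column; both
  conventions can be compared by passing divisor-only `boxSizes`.
* **Ties and boundaries.** `binarize()` sends values *strictly below*
  the threshold to foreground, so a constant mid-gray tile has no
  foreground and `computeFD()` raises a degenerate-input error naming
  the ROI (as it does whenever the skeleton comes out empty).
* **Fits.** With fewer than two distinct box sizes, or an empty mask,
  `boxCount()` refuses rather than extrapolating.
* **Blur borders.** Mirrored ("reflect") borders are the package
  convention. With sigma 35 on a 100-px tile the kernel support
  (±140 px) exceeds the tile, so *no* border policy reproduces a linear
  trend exactly: a 60-gray-level corner-to-corner ramp leaves a
  ±17-level residual after blur-subtraction under mirroring, about half
  that under constant edge extension (`border = "replicate"`, exposed
  on `gaussianBlur()` for comparison). This residual — and, more
  fundamentally, the fact that the method centres the corrected
  histogram exactly at the binarization threshold — makes the final FD
  sensitive at the ±0.03–0.09 level to even small global brightness
  perturbations on single 100-px tiles. Median behaviour across tiles
  is far more stable (median |ΔFD| ≈ 0.015 under a 60-level ramp in the
  package's own harness). Users comparing groups should therefore rely
  on per-group means over many ROIs, exactly as the study design does,
  not on single-tile FD values.

## The cortical-width construction

`measureMCW()` reproduces the classical tracing: the local direction of
the inferior cortical border is estimated as the principal axis (total
least squares) of the border vertices lying within ±50 px (the
`window` argument) of the foramen column; a probe line through the
foramen centre perpendicular to that direction is intersected with the
endosteal and inferior polylines (segment-wise linear interpolation;
the crossing nearest the foramen is used when there are several); the
width is the distance between the crossings times the pixel spacing in
mm. The principal-axis fit, unlike a row-on-column regression, makes
the construction invariant under rigid rotation of the scene (verified
to 1e-6 relative in the tests). MCI grading remains a human visual
assessment; the package only validates grades (C1/C2/C3) and
tabulates them by group for the chi-square test.

## The statistical battery

All group comparisons accept *printed summaries* — (n, mean, SD)
triples — as first-class inputs, because published tables are often the
only data available.

* `tTestFromSummary()` / `tTestPooled()`: equal-variance Student t with
  pooled variance and `n1 + n2 - 2` df. The pooled (not Welch) form is
  used throughout; it is what reproduces published two-group t values
  from summary tables.
* `chiSquareIndependence()`: Pearson chi-square without continuity
  correction; empty margins are dropped with a warning.
* `cohensD()`: standardized mean difference with the
  root-mean-square-of-SDs denominator by default — the two-group
  convention of the G*Power tool — with the pooled-SD variant as an
  option. Published post hoc powers reproduce only under the rms
  convention.
* `posthocPowerT()`: two-sided power from the noncentral t
  distribution, noncentrality `d * sqrt(n1 n2 / (n1 + n2))`. At d = 0
  it returns exactly alpha.
* `iccReliability()`: two-way Shrout–Fleiss ICCs. The default is
  ICC(2,1) — raters random, absolute agreement, single measures — the
  conservative choice when the model is unstated; the mixed/consistency
  form and average-measures units are explicit arguments. Confidence
  intervals come from F-distribution bounds (Satterthwaite df for the
  agreement form).
* `cronbachAlpha()`, `mannWhitney()` (exact for small untied samples,
  tie-corrected normal approximation otherwise), and `twoWayAnova()`
  (Type II sums of squares, so unbalanced sex-by-group designs are
  order-invariant) complete the battery.

```{r stats-example}
tTestFromSummary(groupSummary(15, 1.162, 0.076),
                 groupSummary(45, 1.253, 0.067))
d <- cohensD(c(15, 1.162, 0.076), c(45, 1.253, 0.067))
posthocPowerT(d, 15, 45)
```

## What the synthetic generators emulate — and what they do not

* `makeFractalMask()` builds sets with *known* dimension (filled square
  FD 2, line FD 1, depth-k Sierpinski carpet FD ln 8 / ln 3 with
  exactly 8^k foreground pixels), giving the box-counting engine
  closed-form oracles, plus seeded Bernoulli dot masks for
  property-style comparisons against an exhaustive per-box scan.
* `makeTrabecularTexture()` synthesizes a fractional-Brownian surface
  spectrally (power spectral density proportional to f^-(2H+2)), at a
  fixed contrast of mean 100 / SD 28 gray levels, with an optional
  additive corner-to-corner brightness ramp. The fixed contrast is
  deliberate: textures differing only in `gradientAmplitude` share a
  bit-identical base, so ramp comparisons isolate the illumination
  term, and the level leaves 8-bit headroom for ramps up to ~60 levels.
  Lower Hurst means rougher texture; across seeds the median pipeline
  FD decreases monotonically in H over {0.2, 0.5, 0.8}, mimicking the
  direction real trabecular complexity drives the measure. What fBm
  does *not* emulate: anatomical structure, ghost shadows, spine
  superimposition, machine-specific noise — so passing tests validate
  the measurement chain, not clinical performance on radiographs.
* `makeCortexScene()` renders two parallel cortical band edges a known
  physical width apart at an arbitrary rigid rotation, with consistent
  landmark annotations: a closed-loop harness for `measureMCW()`.
* `makeGroupSamples()` draws per-subject values from per-group normal
  distributions; with `exact = TRUE` the draw is affinely standardized
  so sample moments match the targets exactly, turning summary-derived
  statistics into deterministic targets for end-to-end runs.

Every generator is a pure function of its spec (seed included) and
restores the caller's RNG state.

## The study pipeline

`runStudy()` drives the whole analysis from one YAML config: per
subject it computes FD for each configured ROI and MCW for each
annotated side, tabulates MCI grades, then per variable produces group
summaries, the pooled t, the MCI chi-square, and post hoc power for
the significant variables (all variables with `powerAll = TRUE` —
power-only-when-significant mirrors common reporting practice, and the
per-subject table is always emitted so every table statistic can be
recomputed independently). A subject failing one stage is excluded
from that variable only, with the exclusion logged and counted — a
60-radiograph study should not abort on one bad crop. Outputs are
plain CSVs plus a JSON manifest with a config fingerprint, and rerunning
an identical config yields byte-identical tables.

## Problem sizes and known limitations

The bundled tests and the reproduction script run entirely on
synthetic inputs at desk scale: 100–128 px rasters, 20 seeds for the
texture properties, 50 random masks for the box-count oracle, 10^4
replicates for the type-I calibration of the t and Mann–Whitney tests —
sizes chosen so the full suite completes in a few minutes on one core
while leaving the statistical checks well-powered.

Known limitations: single-tile FD is sensitive to small brightness
perturbations (see the blur-border note above) — group means are the
meaningful quantity; the MCW tangent window (±50 px) assumes the
cortical border is locally straight under the foramen; MCI automation
is out of scope by design; and the synthetic textures validate the
algorithmic chain, not diagnostic accuracy on clinical images.
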