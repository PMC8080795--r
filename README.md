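# trabeculaR

Quantitative analysis of mandibular bone on dental panoramic
radiographs (DPRs), for researchers studying how systemic conditions —
osteoporosis, familial adenomatous polyposis, and other disorders with
osseous jaw manifestations — alter trabecular architecture and the
inferior mandibular cortex.

The package implements three measurement families and the statistics
that connect them to a two-group study design:

* **Box-counting fractal dimension (FD)** of trabecular texture on
  standardized 100 × 100-pixel regions of interest, after the classic
  preprocessing chain: Gaussian blur (σ = 35 px) to estimate the
  large-scale brightness field, subtraction with a +128 gray offset,
  binarization at 128 (bone = dark phase), 3 × 3 morphological
  opening, and topology-preserving skeletonization. Occupied boxes
  N(s) at widths s ∈ {2, 3, 4, 6, 8, 12, 16, 32, 64} are fitted by
  OLS, and

      FD = −slope of ln N(s) on ln s.

* **Mandibular cortical width (MCW)**: the probe line through the
  mental foramen centre, perpendicular to the locally fitted inferior
  cortical border, intersected with both cortical edges; width in mm =
  crossing distance × pixel spacing. The **mandibular cortical index
  (MCI)** (Klemetti C1/C2/C3, a human visual grading) is validated and
  tabulated for chi-square testing.

* **Statistics from raw data or printed summaries**: pooled Student t
  (t = (x̄₂ − x̄₁)/(s_p √(1/n₁ + 1/n₂))), Pearson chi-square without
  continuity correction, Cohen's d with the G*Power rms-SD denominator
  d = |x̄₁ − x̄₂|/√((s₁² + s₂²)/2), post hoc power from the noncentral
  t distribution (δ = d √(n₁n₂/(n₁+n₂))), Shrout–Fleiss ICCs,
  Cronbach's alpha, Mann–Whitney, and Type-II two-factor ANOVA.

Seeded synthetic generators — exact fractals of known dimension,
fractional-Brownian trabecular textures, cortical-band scenes, and
moment-matched group samples — make the whole chain testable without
patient data, and `runStudy()` drives a full config-defined study to
publication-shaped tables.

## Worked example

```r
library(trabeculaR)

## fractal dimension of a seeded trabecular-like texture
img <- makeTrabecularTexture(syntheticSpec("fbm_texture", side = 120,
                                           hurst = 0.5, seed = 7))
computeFD(img, roiSpec("ROI2", 10, 10, 100))
#> FDResult 'ROI2': FD = 1.2358 (fit r^2 = 0.9905)

## two-group comparison straight from printed summaries (n, mean, SD)
tTestFromSummary(groupSummary(15, 1.162, 0.076),
                 groupSummary(45, 1.253, 0.067))
#> Pooled two-sample t: t = 4.4057, df = 58, p = 4.608e-05 (pooled SD 0.06928)

## achieved power at the observed effect size
d <- cohensD(c(15, 1.162, 0.076), c(45, 1.253, 0.067))
posthocPowerT(d, 15, 45)
#> Post hoc power: d = 1.270, ncp = 4.260, t_crit = 2.002 (df 58), power = 98.7%

## cortical width from annotated landmarks (0.1 mm/px, 40 px gap)
lmk <- corticalLandmarks(c(100, 250),
                         inferiorBorder  = cbind(180, seq(150, 350, 10)),
                         endostealMargin = cbind(140, seq(150, 350, 10)),
                         side = "right", spacing = 0.1)
measureMCW(lmk)
#> MCWResult (right): width 4.0000 mm
```

The FD of ~1.24 sits in the range typical of trabecular bone texture
(a filled region gives exactly 2, a line exactly 1); t = 4.41 on 58 df
says the two groups' mean FD differ by far more than their pooled
spread allows under the null; power 98.7% is the probability such a
difference would be detected again at α = 0.05 with these group sizes.

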