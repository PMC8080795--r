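Package: trabeculaR
Title: Box-Counting Fractal Dimension and Radiomorphometric Analysis of
    Mandibular Trabecular Bone
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies trabecular bone texture on dental panoramic
    radiographs. Implements the classic blur-subtract-binarize-skeletonize
    preprocessing chain followed by box-counting fractal dimension
    estimation on standardized 100x100-pixel regions of interest, the
    mandibular cortical width (MCW) measurement from annotated cortical
    landmarks, tabulation of the mandibular cortical index (MCI), and the
    accompanying statistical battery: pooled two-sample t tests from raw
    data or printed group summaries, chi-square tests of independence,
    Mann-Whitney tests, two-factor ANOVA, intraclass correlation
    coefficients, Cronbach's alpha, and noncentral-t post hoc power.
    Includes seeded synthetic-data generators (exact fractal fixtures,
    fractional-Brownian trabecular textures, cortical-band scenes,
    moment-matched group samples) and a config-driven study pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    tools,
    utils,
    grDevices,
    png,
    tiff,
    yaml,
    jsonlite,
    car
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
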