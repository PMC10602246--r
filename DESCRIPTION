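Package: dermaradiomics
Title: Delta-Radiomics Texture Analysis of Radiation Dermatitis from Skin
    Surface Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies acute radiation dermatitis from close-up RGB skin
    surface images. Implements masked circular region-of-interest grey-level
    co-occurrence matrix (GLCM) texture analysis with 18 Haralick-type
    features (two feature dialects), delta-radiomics ratios of every feature
    to its pre-treatment baseline, and the full longitudinal statistical
    harness: two-way repeated-measures ANOVA with Mauchly sphericity testing
    and Greenhouse-Geisser correction, Shapiro-Wilk-gated paired t /
    Wilcoxon signed-rank comparisons with a Bonferroni post-hoc threshold,
    Shapiro-Wilk-gated Pearson/Spearman dose correlations, and
    Benjamini-Hochberg false-discovery-rate control. A seeded synthetic
    cohort generator renders longitudinal skin-texture phantoms with dose-
    and time-dependent darkening and heterogeneity so that the whole
    pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
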