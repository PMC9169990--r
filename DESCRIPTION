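Package: stereolamb
Title: Testicular Stereology and Spermatogenic Efficiency Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative testicular histology for small-ruminant
    immunocastration studies. Computes per-animal morphometric and
    stereological parameters from raw slide measurements (seminiferous
    tubule diameter and epithelium height, point-count volume densities,
    gonadosomatic, leydigosomatic and tubulosomal indices, total
    seminiferous tubule length), applies the Abercrombie section-geometry
    correction to stage-1 germ and Sertoli cell counts, derives intrinsic
    spermatogenic yields, Sertoli cell indices and whole-testis production
    estimates (Sertoli cell number, daily sperm production, testicular
    sperm reserve), and compares treatment groups with a
    normality-branched test choice (ANOVA/Tukey or Kruskal-Wallis/Dunn)
    rendered as compact letter displays. Includes a seeded synthetic
    cohort generator calibrated to published group summaries so the whole
    pipeline is testable without access to raw slide data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
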