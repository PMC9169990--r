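---
title: "Testicular stereology: models, corrections, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testicular stereology: models, corrections, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stereolamb)
```

## The scientific problem

Immunization against GnRH suppresses the hypothalamic–pituitary–gonadal
axis and, with it, spermatogenesis. Whether a vaccine dose actually
castrated an animal is ultimately a histological question: did the
seminiferous epithelium regress, and did sperm production stop?
Quantitative testicular histology answers it with a small set of
stereological estimators computed from routine slide measurements.
This package implements that workflow end to end for the standard
small-ruminant design — a saline control group and one or more vaccine
dose groups, with roughly ten animals per group — together with a
calibrated synthetic-cohort generator so every step can be exercised
and tested without access to raw slide data.

## From slides to per-animal parameters

Each animal contributes four kinds of raw measurements, mirroring
routine bench practice with 3-µm resin sections:

* **Tubule profiles.** Thirty circular seminiferous tubule
  cross-sections, each measured for diameter and for epithelium height
  from the basal membrane to the lumen. Their means are the animal's
  seminiferous tubule diameter (STD, µm) and germinative epithelium
  height (GEH, µm).
* **Point-count fields.** Ten fields scored with a point reticle
  (400 points by default), each point classified into one of six
  compartments: lumen, germinative epithelium, tunica propria, Leydig
  cells, blood vessels, connective tissue. Pooled point fractions
  estimate volumetric proportions; lumen + epithelium + tunica propria
  is the tubular compartment, the rest is intertubular.
* **Stage-1 cell counts.** Ten tubule cross-sections at stage 1 of the
  seminiferous epithelium cycle, counted for type-A spermatogonia (A),
  pre-leptotene/leptotene (PL) and pachytene (PQ) spermatocytes, round
  spermatids (Ar), and Sertoli cell nucleoli (S).
* **Masses.** Body mass and the mass of each testis.

Derived quantities follow the standard formulas. The gonadosomatic
index is $\mathrm{GSI} = 100 \cdot \mathrm{TW}/\mathrm{BM}$ for paired
testis mass TW and body mass BM; the leydigosomatic and tubulosomal
indices replace TW by the mass of the corresponding parenchyma
component. The total length of seminiferous tubules treats the tubular
compartment as a cylinder of diameter STD:

$$\mathrm{TLST} = \frac{V_\mathrm{parenchyma}\; f_\mathrm{tubular}}
{\pi\,(\mathrm{STD}/2)^2},$$

with parenchyma volume from testis mass at density 1.0 g/mL and a
configurable non-parenchyma (albuginea/mediastinum) discount,
default 0. All per-animal quantities are computed per testis **pair**
(TW), and `TLST_per_g` divides by TW; the animal is the experimental
unit throughout, so group summaries are always summaries of per-animal
values.

## The Abercrombie correction and its oracle

A nucleus of diameter $D$ is visible in any section whose slab comes
within $D/2$ of its centre, so raw profile counts overestimate true
counts by the factor $(T+D)/T$ for section thickness $T$. The package
corrects every stage-1 count by $T/(T+D)$, with a per-class mean
nuclear diameter and — deliberately — the **nucleolar** diameter for
Sertoli cells, whose nucleoli rather than nuclei are what gets counted.
The test suite validates the factor against an independent Monte-Carlo
oracle that drops spheres on a line and sections them with a slab,
across $D/T$ from 0 to 5; the length estimator is likewise checked
against a closed-form cylinder phantom that it must invert exactly.

From corrected populations follow the intrinsic yields (A:PL, PL:PQ,
PQ:Ar, A:Ar), the Sertoli indices (S:A … S:CG, with
S:CG = S:A + S:PL + S:PQ + S:Ar by construction), and the
whole-testis production estimates: a corrected per-section count times
$\mathrm{TLST}/T$ sections gives the total Sertoli cell number (NSCT,
from S) and the testicular sperm reserve (TSR, from Ar). Daily sperm
production divides TSR by a time-equivalent of one reserve turnover,
10.5 days by default — chosen because the published control-group
reserve/production ratio is 10.51, an internal-consistency choice
rather than a measured cycle duration for these lambs; it is a
configurable constant, as are the theoretical expansions (256 round
spermatids per type-A spermatogonium; 4 per pachytene spermatocyte)
behind `general_yield_percent()` and `meiotic_loss_percent()`.

Ratios in regressed tubules follow the reporting convention of the
field: $0/0$ is a structural zero (a fully regressed class), while a
positive count over a zero denominator is undefined — it is excluded
from group summaries with a warning rather than silently zeroed.

## Group comparison

The statistical workflow reproduces the conventional
normality-branched analysis. For each variable, a Shapiro–Wilk test on
the pooled within-group residuals chooses the branch: parametric
(one-way ANOVA with Tukey HSD) or nonparametric (Kruskal–Wallis with
Dunn's pairwise z-tests, tie-corrected, Holm-adjusted). Residual-based
normality testing is used because ten animals per group leave
per-group tests underpowered; `choose_branch(..., method =
"per_group")` switches to the stricter convention. Group summaries
match the branch — mean ± SD or median ± IQR — and the pairwise matrix
is rendered as a compact letter display (insert-and-absorb), with the
invariant, enforced by property tests, that two groups share a letter
exactly when their pairwise p-value is not below α. Constant variables
(e.g. sperm production in fully castrated groups compared with
themselves) cannot be tested and are reported untested with all groups
sharing "a". No correction is applied across variables, matching the
reporting convention the workflow emulates.

Calibration of both branches is part of the acceptance suite: under a
three-group null with n = 10 the omnibus type-I error must land in
[0.03, 0.07] at α = 0.05 over 2000 replicates, and at the published
effect sizes the a/b/b letter pattern (control apart, doses tied) must
be recovered in at least 95% of 1000 seeds for testis weight, STD and
GEH.

## What the synthetic generator emulates

`default_generator_params()` encodes the study conditions the package
is calibrated to: three groups of ten lambs, 30 profiles, 10 fields of
400 points, 10 stage-1 cross-sections per animal, 3-µm sections.
Distribution families were chosen for positivity and the
overdispersion visible in published between-animal SDs:

* masses are lognormal (body mass back-solved from published TW and
  GSI — 16.6, 17.1 and 15.5 kg per group — with a 15% CV, since body
  mass itself is never published; per-testis masses are half the
  paired mean with the paired SD split over two independent testes);
* lengths (diameters, heights) are zero-truncated normal with a
  between-animal level set to the published SD and a within-animal
  level of 8% (diameter) or 10% (height) of the group mean — typical
  profile-to-profile spread for circular cross-sections; epithelium
  heights are clamped to the tubule radius so every profile is
  geometrically possible;
* point counts are Dirichlet-multinomial: each animal draws its own
  compartment composition from a Dirichlet with total concentration 15
  (matching the published between-animal spread of the epithelium
  proportion), then fields are multinomial;
* stage-1 counts are gamma-Poisson: an animal-level mean with the
  published CV, Poisson counts around it per cross-section. Raw count
  means are the published **corrected** means pushed back through
  `inverse_abercrombie()`, so generator and correction are mutually
  consistent whatever nuclear diameters are assumed. The diameters
  themselves (A 6.9, PL 6.2, PQ 9.5, Ar 5.3 µm; Sertoli nucleolus
  3.0 µm) are typical for lamb testis histology, as they are not
  published with the summaries. A mean of zero produces structural
  zeros — the fully regressed pachytene/spermatid classes of
  vaccinated groups.

The whole cohort is drawn from a single RNG stream in group and animal
order, so a seed fixes every byte of the output CSVs.

The generator emulates the *statistical* structure of the study, not
its physics: there is no spatial tissue geometry, no image content, no
section-to-section correlation, no measurement error model beyond the
within-animal spread, and no longitudinal (pre/post-dose) dimension.
Passing calibration tests therefore show that the pipeline's
estimators are unbiased for data with this structure — they do not
validate the histological measurement process itself.

## Numerical and design choices

* **Calibration targets and the simultaneous band.** The generator is
  calibrated so that the pipeline recovers, at 200 simulated animals
  per group, the published group means of STD, GEH and the five
  corrected populations. With 18 noisy targets, requiring each to land
  within 2 Monte-Carlo SEs individually would fail on most seeds for a
  perfectly calibrated generator (joint coverage $0.954^{18} \approx
  0.43$), so the acceptance test uses the simultaneous 95% band
  ($|z| \le z^*$ with $z^* = \Phi^{-1}(1 - 0.025/18) \approx 2.91$),
  which holds the family-wise level the per-target band intends.
  Structural zeros are asserted exactly.
* **Published inconsistencies.** The published LSI, TSI and TLST-per-
  gram control values are mutually inconsistent with the published
  testis weight, GSI and volumetric proportions under any single
  standard formula (e.g. plugging the published control means into the
  length formula gives ≈ 3078 m against a published per-animal mean of
  3835.7 m — an averaging-order effect at best, an unstated constant
  at worst). The package implements the standard formulas and treats
  those published rows as context, never as assertion targets; the
  reproducible targets are the direct measurements (STD, GEH,
  proportions, corrected counts) and the derived percentages.
* **Rendering.** Tables round half-even to a configurable number of
  decimals; letters are attached only when groups actually differ.
  Table 6 is displayed on the conventional 10⁹/10⁶ scales.
* **Problem sizes.** The test suite simulates 200 animals per group
  for calibration, 2000 replicates for type-I error, 1000 seeds for
  the letter-pattern power check, and 5 × 10⁵ spheres per geometry for
  the sectioning oracle — sizes at which Monte-Carlo error is well
  below each assertion's tolerance.

## Known limitations

Tissue shrinkage during processing is not modelled (none was applied
in the emulated protocol); stage-1 identification is assumed upstream;
elongated spermatids are not accounted (the reserve is the round-
spermatid population at stage 1); and the 10.5-day turnover equivalent
is a consistency constant, not a measured kinetic parameter — absolute
DSP values inherit its uncertainty even though group contrasts do not.

## A minimal session

```{r example, eval = FALSE}
params <- default_generator_params()
ds <- generate_cohort(cohort_design(n_per_group = 10, seed = 1), params)
res <- run_pipeline(ds)
res$tables$table1
res$comparisons$TW$letters
worked_examples()
```
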