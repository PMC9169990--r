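# stereolamb

Quantitative testicular histology for small-ruminant immunocastration
studies.

Whether an anti-GnRH vaccine actually castrated a lamb is, in the end,
a histological question. `stereolamb` takes the raw slide measurements
a histologist produces — seminiferous tubule profiles, point-count
fields over tissue compartments, stage-1 cell counts, nuclear
geometry, and organ masses — and computes the full panel of
stereological parameters used to judge spermatogenic activity, then
compares treatment groups the way the field reports them: compact
letter displays over a normality-branched test choice.

The core quantities, per animal:

* **Morphometry** — seminiferous tubule diameter (STD) and germinative
  epithelium height (GEH) as means over 30 circular cross-sections;
  volumetric proportions of six parenchyma compartments from
  point counting; gonadosomatic, leydigosomatic and tubulosomal
  indices (GSI = 100·TW/BM and its component analogues); total
  seminiferous tubule length TLST = V·f / (π·(STD/2)²), per testis
  pair and per gram.
* **Cytometry** — stage-1 counts corrected for section geometry with
  the Abercrombie factor T/(T+D) (nucleolar diameter for Sertoli
  cells); intrinsic yields (A:PL, PL:PQ, PQ:Ar, A:Ar) against the
  theoretical 256-fold expansion; Sertoli indices (S:A … S:CG); and
  whole-testis production estimates — Sertoli cell number (NSCT),
  testicular sperm reserve (TSR = corrected round spermatids ×
  TLST/T), daily sperm production (DSP = TSR / 10.5 d).
* **Statistics** — Shapiro–Wilk on pooled residuals chooses
  ANOVA + Tukey HSD or Kruskal–Wallis + Dunn (Holm-adjusted); groups
  sharing no letter differ at α = 0.05.

A seeded synthetic-cohort generator, calibrated to published group
summaries for anti-GnRH-immunocastrated Santa Inês lambs (three groups
of ten: saline control, 1.0 mL and 0.5 mL doses), makes the whole
pipeline testable without access to raw slide data.

## Worked example

```r
library(stereolamb)

params <- default_generator_params()          # calibrated study conditions
ds <- generate_cohort(cohort_design(n_per_group = 10, seed = 1), params)
res <- run_pipeline(ds)
res$tables$table1
```

```
   variable           control     vaccine_1.0mL     vaccine_0.5mL P_value
         TW   88.24 ± 23.04 a   26.06 ± 18.35 b    19.99 ± 6.40 b   0.000
        GSI     0.56 ± 0.20 a     0.17 ± 0.08 b     0.13 ± 0.05 b   0.000
        STD  205.96 ± 16.93 a   97.35 ± 21.86 b   72.60 ± 18.89 c   0.000
        GEH    47.35 ± 2.40 a    10.73 ± 3.36 b     9.82 ± 1.38 b   0.000
        LSI       0.01 ± 0.03       0.00 ± 0.00       0.00 ± 0.00   0.233
        TSI     0.48 ± 0.21 a     0.15 ± 0.08 b     0.12 ± 0.05 b   0.000
       TLST 2377.33 ± 1120.53 3024.44 ± 2678.05 4272.73 ± 5573.17   0.140
 TLST_per_g    27.10 ± 6.73 a  115.73 ± 27.83 b 189.39 ± 249.20 b   0.000
```

Each cell is the group mean ± SD (median ± IQR for nonparametric
variables) of a per-animal quantity; letters mark significant pairwise
differences, so testis weight collapses under both doses (a/b/b) while
this particular seed even separates the two doses on tubule diameter
(a/b/c). Production estimates behave the same way:

```r
res$tables$table6   # NSCT/DSP/TSR on the 1e9 / 1e6 display scales
```

```
   variable           control   vaccine_1.0mL   vaccine_0.5mL P_value
       NSCT     4.76 ± 2.52 a 15.46 ± 9.15 ab 25.74 ± 15.85 b   0.001
 NSCT_per_g     0.05 ± 0.01 a   0.45 ± 0.20 b   1.04 ± 1.24 b   0.000
        DSP     3.58 ± 2.43 a   0.00 ± 0.00 b   0.00 ± 0.00 b   0.000
  DSP_per_g   40.21 ± 13.71 a   0.00 ± 0.00 b   0.00 ± 0.00 b   0.000
        TSR   37.55 ± 25.54 a   0.00 ± 0.00 b   0.00 ± 0.00 b   0.000
  TSR_per_g 422.17 ± 143.93 a   0.00 ± 0.00 b   0.00 ± 0.00 b   0.000
```

Sperm reserve and daily production are exact zeros in the vaccinated
groups because their pachytene and spermatid classes are structurally
absent — Sertoli numbers rise only because tubule shrinkage inflates
TLST.

The headline effect sizes derived from the published group summaries:

```r
round(worked_examples(), 2)
#>      std_reduction_1.0mL      std_reduction_0.5mL            gsi_reduction
#>                    55.23                    57.02                    80.30
#>       geh_mean_reduction min_reduction_both_doses        general_yield_pct
#>                    77.16                    55.23                    21.01
#>         meiotic_loss_pct
#>                    21.00
```

i.e. both doses reduce tubule diameter by over 55% and GSI by 80%,
every regressing morphometric variable drops by more than half, and a
normal control realizes 21% of the theoretical 256-fold spermatid
expansion with 21% meiotic losses.

## Command line

```sh
inst/cli/stereolamb simulate --seed 1 --out raw/
inst/cli/stereolamb analyze  --in raw/ --out results/ --format markdown
inst/cli/stereolamb reproduce-worked-examples
```

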