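# melmorph

Objective tumour morphometrics from melanoma segmentation masks, and the
survival analysis to evaluate them.

When a segmentation model labels every pixel of a scanned slide as
*invasive melanoma* or not, the resulting binary mask holds more geometry
than the single hand-measured depth (Breslow thickness) that currently
dominates melanoma staging. melmorph derives five biomarkers from such a
mask and runs the full right-censored survival workflow a biomarker
evaluation needs. It is aimed at digital-pathology and biostatistics
groups who have per-case masks (or polygon annotations) plus a cohort
table with survival endpoints.

For the largest connected piece of segmented tumour (robust to serially
sliced specimens), melmorph computes:

| biomarker | definition |
|---|---|
| area (mm²) | foreground pixels × pixel footprint |
| perimeter (mm) | length of the sub-pixel outer contour |
| major axis length (mm) | longer side of the minimum-area enclosing rectangle |
| digital Breslow thickness, dBT (mm) | shorter side of that rectangle |
| Nodularity Index, NI | dBT / major axis ∈ (0, 1] |

The rectangle comes from the rotating-calipers construction on the convex
hull of the tumour outline: the minimum-area enclosing rectangle has one
side collinear with a hull edge, so scanning hull edges finds it exactly.
NI is a size-independent shape metric — depth per unit width — and dBT is
named for its high rank correlation (ρ ≈ 0.89) with conventional Breslow
thickness.

The statistics stage produces quartile Kaplan–Meier curves with log-rank
tests, Cox proportional-hazards models of each log-transformed biomarker
(unadjusted, and adjusted for age, sex and anatomical site) with Wald and
bootstrap-percentile intervals, Harrell's concordance index, Schoenfeld
proportional-hazards diagnostics, five-year logistic/ROC model
comparisons, collinearity checks and Wilcoxon subgroup contrasts — with a
family-wise significance threshold of p ≤ 0.001.

A synthetic module generates tumour masks of known analytic geometry
(ellipses, nodular blobs, superficial strips, fragmented lesions) and
survival cohorts with calibrated structure (30% deaths, 5.7-year median
follow-up, a Gaussian-copula biomarker joint with the dBT↔Breslow rank
correlation at 0.89, Weibull proportional hazards with documented effect
sizes), so the entire pipeline is testable without clinical data.

## Worked example

```r
library(melmorph)

## geometry: a rotated 12 x 3 mm (semi-axes) ellipse rasterized at 20 um/px
g   <- generate_shape(shape_spec("ellipse", a = 12, b = 3,
                                 rotation = 25, mpp = 20, seed = 42))
rec <- compute_morphometrics(g$mask)
rec
#>          case_id area_mm2 perimeter_mm major_mm dbt_mm     ni n_components
#> 1 ellipse_a12_b3    113.1        51.51       24  6.004 0.2502            1
#>   largest_fraction rect_angle_deg
#> 1                1          25.02
```

The analytic values are area πab = 113.10 mm², major 2a = 24 mm, minor
2b = 6 mm, NI = 0.25; the record recovers each to ≲ 0.1%, and the logged
rectangle angle matches the 25° rotation.

```r
## statistics: a synthetic cohort whose dBT effect is HR 2.04 per log-unit
sim <- generate_cohort(cohort_spec(n = 2000, designated_param = "dbt",
                                   endpoint = "OS", seed = 1))
fit_cox(sim$cohort, "dbt", "OS", adjusted = TRUE)
#> Cox adjusted model, OS, log(dbt): HR 2.001 (95% CI 1.767-2.266),
#>   p = 7.6e-28, C = 0.671, n = 2000 (600 events, 0 dropped)

spearman_rho(sim$cohort$dbt_mm, sim$cohort$breslow_mm)
#> [1] 0.890
```

The adjusted model recovers the generating hazard ratio (2.04 lies inside
the 95% CI) with a concordance of 0.67, and the simulated gold-standard
Breslow column correlates with dBT at the calibrated ρ = 0.89.

For an end-to-end run (masks → morphometrics → merged cohort → report
JSON, figures and log) use `run_pipeline()`, or the installed command-line
tool:

```sh
exec/melmorph all --mode synthetic --out results_dir --seed 7
exec/melmorph morph --masks masks_dir --mpp 0.25 --out morphometrics.csv
```

## Layout

* `R/`, `src/` — mask/region I/O, morphometry (contours, hulls,
  rotating calipers), survival workflow, synthetic generator, pipeline.
* `exec/melmorph` — thin CLI over the package functions
  (`simulate`, `morph`, `cohort`, `survival`, `all`).
* `vignettes/melmorph-methods.Rmd` — the model, its assumptions,
  numerical choices and limitations.
* `tests/testthat/` — unit, property and acceptance tests (geometry
  against brute-force oracles, statistics against enumeration,
  parameter-recovery against the generator's sealed truth records).
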