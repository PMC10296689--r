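# mifTME

Quantitative analysis of the tumour immune microenvironment (TME) from
multiplex immunofluorescence (mIF) single-cell exports, built around the
question of whether PD-L1-high (tumour proportion score ≥ 50%)
*ALK*-rearranged non-small cell lung cancers carry an immunosuppressive
microenvironment — enriched regulatory T cells (Tregs, CD4+FOXP3+) and
exhausted CD8+ T cells (CD8+PD-1+), sitting close to tumour cells — and
whether those features predict progression-free (PFS) and overall
survival (OS) under ALK-TKI therapy.

The package is aimed at analysts who receive inForm-style per-cell tables
(coordinates in μm plus boolean marker calls) and a clinical table, and
want the full published analysis plan as reproducible code.

## What it computes

* **Phenotyping** — fixed boolean gates over two six-marker panels
  (PANCK/CD4/CD8/FOXP3/PD-1/DAPI and PANCK/CD3/CD20/CD56/CD68/DAPI) into
  eight immune populations plus tumour cells, with PANCK precedence and
  subset counting (Treg ⊂ CD4 T; exhausted CD8 ⊂ CD8 T).
* **Regions** — tumour (union of malignant-nest polygons, closed),
  stroma, and the invasive margin: the band within 250 μm of the
  tumour/host border, split into IM-T and IM-S by the sign of the border
  distance.
* **Spatial metrics** — per tumour cell, the nearest-neighbour distance
  (NND) to each immune population and the count of immune cells within a
  30 μm radius (inclusive), pooled per patient over 2–3 ROIs, with an
  explicit "not computable" state when a population is absent.
* **Composition** — counts, densities (cells/mm²) and proportions per
  patient × region × population, and the Treg/CD8 ratio.
* **Cohort statistics** — Mann–Whitney U (exact for small untied
  groups), Spearman correlation with the |ρ| > 0.60 strong-correlation
  rule, two-sided Fisher exact (point-probability rule), Pearson
  chi-squared without Yates correction for ORR/DCR, response rates, and a
  baseline-characteristics table builder.
* **Survival** — Kaplan–Meier with medians and log-log CIs, log-rank
  tests, Cox models (Breslow ties by default) with the univariate
  p < 0.05 → multivariate selection rule, and maximally selected
  log-rank cutpoints: the marker split maximising the standardized
  statistic (O−E)/√V over all admissible splits.
* **Synthetic cohorts** — `simulate_cohort()` generates patients,
  nest geometries and cells with planted ground truth (Treg rates
  2.55×10⁻³ vs 6.6×10⁻⁵ by PD-L1 group; planted PFS hazard ratio 2.792
  for PD-L1-high), so the whole pipeline is testable end to end.

See `vignettes/tme-methods.Rmd` for the model conventions and their
rationale.

## Worked example

```r
library(mifTME)

# an mIF-style synthetic cohort: 18 patients, 10:8 PD-L1 high:low
coh <- simulate_cohort(simulation_config(n_patients = 18,
                                         prop_pdl1_high = 10/18), seed = 1)
coh
#> <synthetic_cohort> 18 patients, 42 ROIs, 68076 cells

cells <- annotate_regions(phenotype_cells(coh$cells), coh$geometries)
hi <- coh$patients$patient_id[coh$patients$pdl1_group == "high"]
lo <- setdiff(coh$patients$patient_id, hi)
population_proportion(cells[cells$patient_id %in% hi, ], "TREG")
#> [1] 0.00242    # pooled Treg fraction, PD-L1 high group
population_proportion(cells[cells$patient_id %in% lo, ], "TREG")
#> [1] 8.24e-05   # PD-L1 low group: ~30-fold lower, as planted

patient_spatial_summary(cells[cells$patient_id == hi[1], ], "TREG")
#>   patient_id population mean_nnd_um mean_count_within_radius n_tumour_cells
#> 1       P001       TREG    277.3584              0.006479482            926
#>   n_target_cells computable
#> 1              6       TRUE
```

Patient-level survival modelling on a larger simulated cohort:

```r
pts <- simulate_patients(simulation_config(n_patients = 300), seed = 1)
stratified_km_report(pts, "pdl1_group", "pfs")$summary
#>   group   n events    median       lcl       ucl
#> 1  high  77     72  4.055799  2.589985  6.376844
#> 2   low 223    173 11.650042 10.220759 13.830189

res <- univariate_screen_then_multivariate(pts, "pfs")
res$multivariate
#> <cox_result> ties = breslow, iter = 4
#>     variable   coef    hr   lcl   ucl         p
#>     met_bone 0.7964 2.217 1.688 2.913 1.055e-08
#>  met_adrenal 0.7050 2.024 1.173 3.491 1.125e-02
#>    pdl1_high 1.0739 2.927 2.184 3.923 6.738e-13
```

The PD-L1-high group's KM median PFS is far below the low group's, and
the multivariate hazard ratio for PD-L1-high (2.93, 95% CI 2.18–3.92)
recovers the planted 2.792; bone metastasis (planted HR 2.123) is
likewise selected, with the occasional spurious candidate (here adrenal
metastasis) slipping past the univariate 0.05 gate, as expected at that
threshold.

Contingency statistics use the standard containers:

```r
fisher_exact_2x2(matrix(c(28, 10, 12, 2), 2))
#> Fisher exact (two-sided)
#>   statistic = 0.47287, p = 0.4753, n = 52
```

A thin command-line wrapper for simulate/analyze lives at
`inst/scripts/tme_pipeline.R`; `run_pipeline()` is the programmatic
entry point and writes `composition.csv`, `spatial_summary.csv`,
`stats_report.csv`, `survival_report.csv`, `cox_report.csv` and a
`manifest.json` with a config hash and per-stage row counts.

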