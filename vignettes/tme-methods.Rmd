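---
title: "Methods: quantifying the tumour immune microenvironment from multiplex immunofluorescence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying the tumour immune microenvironment from multiplex immunofluorescence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mifTME)
```

## The problem

Multiplex immunofluorescence (mIF) yields, per tissue section, a table of
segmented cells with micrometre coordinates and boolean positivity calls
for a small marker panel. In advanced *ALK*-rearranged non-small cell lung
cancer, the clinical question driving this package is whether tumours with
high PD-L1 expression (tumour proportion score ≥ 50%) harbour a more
immunosuppressive microenvironment — more regulatory T cells (Tregs,
CD4+FOXP3+) and exhausted CD8+ T cells (CD8+PD-1+), sitting closer to
tumour cells — and whether those features track progression-free and
overall survival under ALK TKI therapy.

`mifTME` implements the full desk-side analysis: phenotyping,
tumour/stroma/invasive-margin compartmentalisation, proximity metrics,
composition summaries, the cohort statistical plan, and survival
modelling, together with a synthetic-cohort generator so that every stage
is testable without patient material.

## Phenotyping

Two six-marker panels are stained on sequential sections: Panel 1 (PANCK,
CD4, CD8, FOXP3, PD-1, DAPI) and Panel 2 (PANCK, CD3, CD20, CD56, CD68,
DAPI). Populations are fixed boolean gates: CD4 T cells (CD4+), CD8 T
cells (CD8+), Tregs (CD4+FOXP3+), exhausted CD8 T cells (CD8+PD-1+), CD3
T cells, B cells (CD20+), NK cells (CD56+), macrophages (CD68+), tumour
cells (PANCK+). Three conventions matter and are deliberate:

* **PANCK precedence.** A cell positive for PANCK and an immune marker is
  counted as a tumour cell only. PANCK defines the malignant parenchyma;
  epithelial/immune double positives are overwhelmingly segmentation
  artefacts at cell boundaries.
* **Subset counting.** Tregs also count as CD4 T cells, and exhausted CD8
  T cells as CD8 T cells, because the parent gates are defined by the
  single lineage marker with no exclusion. Whether CD4 totals should
  exclude FOXP3+ cells is genuinely ambiguous in practice; the subset
  convention is the package default and the population indicators make
  the alternative a one-line filter.
* **DAPI gate.** Only DAPI-positive (nucleated) cells are retained;
  `filter_cells()` applies this and an ROI-bounds check before any
  downstream computation.

Panels are analysed independently; no cross-section cell matching is
attempted (the sections are different physical slices).

## Regions: tumour, stroma, invasive margin

The tumour region of an ROI is the union of malignant-nest polygons; the
stroma is the remainder. The tumour/host **border** is the boundary of
that union, and the **invasive margin** is the band within 250 μm
(inclusive) on each side of it, split into IM-T (tumour side) and IM-S
(stroma side). Conventions:

* Boundary cells are tumour (closed tumour region): nests include their
  rim. The band test is inclusive (|d| ≤ 250 μm); both choices make
  results deterministic under exact-boundary coordinates.
* Distances are 2-D Euclidean in micrometres. Real imports must be
  pre-scaled to μm; the synthetic data are generated in μm.
* The margin is computed from the boundary of the full tumour union, not
  per nest. With the generator's disjoint nests these coincide.
* When no geometry is available but the export carries a compartment
  column, compartments are taken as given and the invasive-margin
  analysis is skipped with a warning.

Internally, compartment and margin labels come from one signed
border-distance pass (point-in-polygon by even-odd ray casting with an
explicit on-edge test, plus exact point-to-segment distances). Exact
areas (shoelace) are used for tumour/stroma densities; invasive-margin
areas use deterministic 200×200 grid quadrature per ROI, accurate to a
few percent at the default resolution, which is well below the Poisson
noise of any realistic cell count.

## Spatial metrics

For each **tumour** cell (reference), two quantities are computed against
each immune population (target):

* **NND** — the Euclidean distance to the nearest target cell;
* **radius count** — the number of target cells within 30 μm
  (inclusive), a distance over which direct cell-cell contact is
  plausible.

Per-patient summaries pool the patient's 2–3 ROIs as one sample: the
means are taken over all tumour cells across ROIs, but distances are only
ever computed within an ROI — cells in different physical fields are
never matched. A patient with no cell of the target population anywhere
is flagged **not computable** for NND (no distance is fabricated; the
patient drops out of NND group comparisons, exactly as patients without
computable Tregs drop out of the motivating analysis); the radius counts
are still defined (all zero). Whether the per-patient NND summary should
be the mean or the median over tumour cells is not fixed by convention;
the package uses the mean.

The implementation buckets target cells on a square grid (cell size =
radius for counts; ring-expansion search for NND) and falls back to the
exhaustive scan for small inputs; the two paths are required by the test
suite to agree **exactly**, instance by instance.

## Composition

Counts, densities (cells/mm² of the region, when geometry is known) and
proportions are tabulated per patient × region × population, pooling
ROIs. The proportion denominator is **all retained cells in the region**,
tumour cells included; this matches the order of magnitude (10⁻³–10⁻⁵)
of published mIF percentages. An immune-cells-only denominator is
available (`denominator = "immune"`). The Treg/CD8 ratio divides Treg by
CD8 T-cell counts and is undefined (patient excluded, with a warning)
when the region has no CD8 T cell.

## Cohort statistics

* **Mann–Whitney U** for group comparisons of composition and spatial
  metrics: exact null enumeration when both groups have ≤ 20
  observations and no ties, otherwise the tie-corrected normal
  approximation without continuity correction (so the branches agree to
  within ~0.01–0.02 where they overlap).
* **Spearman correlation** with the strong-correlation rule |ρ| > 0.60;
  exact permutation p for n ≤ 9 without ties, t-approximation otherwise.
* **Fisher exact (2×2)**, two-sided by the point-probability rule: the
  p-value sums hypergeometric probabilities of all margin-compatible
  tables no more probable than the observed one. This reproduces every
  published baseline-table p-value to three decimals.
* **Pearson chi-squared without Yates correction** for response rates.
  The uncorrected statistic reproduces the published ORR/DCR p-values
  (0.202, 0.065); the corrected one does not. Correction is available by
  flag.
* A **Freeman–Halton** r×c exact test backs the three-level ECOG row of
  the baseline table.
* No multiple-testing adjustment anywhere: the analysis plan tests each
  hypothesis at a plain two-sided 0.05.

## Survival analysis

Kaplan–Meier estimation, the log-rank test and Cox proportional-hazards
models are delegated to the `survival` package behind thin, validated
wrappers; the scientific conventions are set here:

* KM medians are the earliest time with S(t) ≤ 0.5 (`NA` = not reached);
  median CIs use the complementary log-log transform.
* Cox ties are handled by **Breslow** by default (the default of the
  mainstream commercial software used for the motivating analyses);
  Efron is available by flag.
* **Univariate → multivariate selection**: each candidate (age ≥ 65,
  sex, smoking, stage, ECOG 1–2, six metastasis sites, PD-L1 ≥ 50%, TKI)
  is fitted alone; candidates with two-sided p < 0.05 enter the joint
  model. An empty selection returns the univariate table with a note.
* PFS and OS have different time origins (TKI start vs diagnosis) and
  are stored as separate time/event pairs; neither is derived from the
  other.

### Maximally selected cutpoints

Continuous markers (e.g. a patient's Treg proportion) are dichotomised at
the value maximising the absolute standardized two-group log-rank
statistic (O−E)/√V over all splits `value ≤ c` vs `value > c` between
consecutive distinct values, subject to `minprop` (default 0.1, the
conventional default of the cutpoint function named in the analysis
plan) of subjects on each side. Ties in the statistic break toward the
lower cutpoint. No installed package provides this search, so it is
implemented directly and verified against exhaustive `survdiff`
evaluation of every admissible split. The post-selection log-rank p-value
is reported as-is — mirroring common practice — and is optimistic; the
pipeline logs a warning to that effect.

## The synthetic cohort generator

The generator emulates the *structure* of the study data so that every
downstream stage has a ground truth:

* **Patients** (default n = 52, P(PD-L1 high) = 12/52): demographics,
  metastasis flags, ECOG, TKI and PD-L1 TPS drawn to match the published
  baseline frequencies; RECIST best response drawn per group (ORR/DCR
  70%/97.5% low, 50%/83.3% high); PFS and OS from exponential
  proportional-hazards models with planted log hazard ratios — PFS HR
  2.792 for PD-L1 high and 2.123 for bone metastasis, OS HR 3.348 for
  PD-L1 high and 6.420 for ECOG 1–2 — and independent exponential
  censoring (median follow-up ≈ 37 months). The exponential baseline
  (rather than Weibull) gives closed-form medians (ln 2 / λ) that the
  tests exploit; baselines are λ = ln 2/16.4 per month for PFS and
  ln 2/70 for OS, so the low-risk OS median is typically not reached
  within follow-up.
* **Geometry**: each patient owns 2–3 ROIs (uniform choice; the original
  ROI-selection rule is unstated, so uniform is the least-informative
  choice) of 1 mm²; each ROI carries 3 disjoint disc nests of radius
  100–220 μm (rejection-sampled with a 25 μm clearance). Discs are the
  simplest geometry with a non-trivial border; disjointness makes the
  union boundary exactly the set of nest rings, avoiding polygon-union
  computation. With these radii every tumour cell lies within 250 μm of
  the border, i.e. IM-T covers the tumour compartment — small-biopsy
  nests behave the same way.
* **Cells**: homogeneous Poisson placement per compartment (defaults
  2000/mm² tumour, 1500/mm² stroma — typical NSCLC section densities);
  each cell draws one population profile from its (PD-L1 group ×
  compartment) stratum and receives the corresponding boolean marker
  calls (intensities are upstream software's business and are not
  modelled). Planted rates: Tregs 2.55×10⁻³ (high) vs 6.6×10⁻⁵ (low),
  exhausted CD8 1.31×10⁻³ vs 1.65×10⁻⁴ — the published group contrast —
  with group-independent lineage rates at realistic magnitudes.
* **Reproducibility**: one root seed; per-patient and per-ROI substreams
  derived by counter, so enlarging the cohort leaves existing patients'
  draws untouched.

What the generator does **not** emulate: marker intensities and spectral
unmixing noise, serial-section misalignment, spatial clustering of immune
cells beyond compartment effects (placement is Poisson within
compartment), correlation between PFS and OS within a patient, and
irregular (non-disc) nest shapes. Passing tests therefore demonstrate the
*computational* correctness of the pipeline and its statistics under the
assumed data structure — not robustness to the messiness of real mIF
exports.

## Numerical choices and degenerate inputs

* Point-in-polygon boundary tolerance 10⁻⁹ μm; border distances exact to
  machine precision against a scalar segment-distance oracle.
* Cox fits run Newton iterations to a 10⁻⁹ convergence tolerance (up to
  50 iterations); non-convergence warnings are caught and attached to
  the result.
* Degenerate inputs fail loudly and specifically: empty compartments,
  zero CD8 denominators, constant markers, single-group log-rank calls,
  constant covariates, out-of-bounds cells and malformed event flags
  each raise a classed condition naming the offending field, file or
  row. Empty target populations are "not computable", never zero-filled.
* All CSV/JSON writers render doubles at 17 significant digits so files
  round-trip bit-exactly.

## Problem sizes used in the checks

The test-suite and acceptance checks run at sizes chosen to make their
statistical assertions sharp while staying desk-scale: composition-rate
recovery at 10⁶ cells (3 binomial SDs), the KM closed-form check at
n = 5000 (±5%), Cox null coverage at 100 replicates of n = 100, planted
hazard-ratio recovery at 50 replicates of n = 500 (coverage compared
against a 3-SD binomial band around 0.95, selection rate ≥ 90%), spatial
oracle equivalence on 50 instances of up to 500 cells, and cutpoint
oracle equivalence on 25 instances of up to 200 subjects.

## Known limitations

* The pipeline consumes boolean positivity calls; gating/thresholding
  optimisation is out of scope.
* Compartment areas for the invasive margin are quadrature estimates,
  not exact geometry.
* The cutpoint-stratified survival reports inherit the optimism of
  maximally selected statistics; no selection-bias correction is
  applied.
* The generator's survival draws for PFS and OS are independent, so
  joint statements across the two endpoints (e.g. PFS/OS concordance)
  are outside what the synthetic cohort can support.
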