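# highmt

Quality-control filters in cancer single-cell RNA-seq routinely discard cells
whose mitochondrial RNA fraction (pctMT) exceeds a threshold such as 15%, on
the assumption that high pctMT marks dying or broken cells. In tumors this
assumption is shaky: malignant cells often carry genuinely elevated
mitochondrial expression, so a blanket pctMT filter can delete a viable,
metabolically distinct — and therapeutically relevant — subpopulation.

`highmt` implements the analytical pipeline for identifying and
characterizing these **HighMT** malignant cells:

- **pctMT-free quality control** — per-patient outlier removal at 5 raw
  median absolute deviations on log1p total counts, log1p genes detected and
  the top-50-gene count fraction, plus absolute bounds (1500–50,000 counts,
  ≥500 genes); mitochondrial identity is never consulted. The traditional
  pctMT > 15% filter is provided only for strategy comparison.
- **HighMT case/control annotation** — cells with pctMT > 15% are HighMT;
  each patient's enrichment of HighMT cells in the malignant vs TME
  compartment is summarized by the odds ratio
  `OR = (n(HighMT,mal)/n(LowMT,mal)) / (n(HighMT,TME)/n(LowMT,TME))`,
  and a patient is a *case* when OR > 2 and ≥15% of malignant cells are
  HighMT (patients with <30 cells in a compartment or <20 HighMT cells are
  excluded).
- **Bin-controlled signature scoring** (Tirosh/Scanpy style: 25 expression
  bins, 50 control genes per signature gene), meta-signatures by gene-set
  intersection, and point-biserial association with HighMT status.
- **Metacells** — disjoint, homogeneous groups of ~25 same-type cells
  (PCA + k-means surrogate) with exact count conservation; metacells are
  HighMT if >30% of members are HighMT and malignant if >50% are malignant.
- **Bulk vs "bulkified"** — per-patient pseudobulk vectors are regressed on
  paired bulk expression with a polynomial whose degree is picked at the
  elbow of the R² curve; the mean residual of MT genes under a non-MT-trained
  model is tested against an empirical null built by resampling gene sets
  from the top-500 expressed genes (B = 500), with Bonferroni or BH
  correction across patients.
- **Pathway dysregulation** — per-pathway HighMT−LowMT median score deltas
  across studies, Ward-linkage clustering, and the xenobiotic phase I/II/III
  comparison.
- **Drug association** — per-cancer-type Pearson correlation between
  cell-line pctMT and IC50 with Student-t significance, per-drug median
  ranking (top/bottom 15), Fisher-exact target-category enrichment, and a
  within-type permutation calibration of the correlation tails.
- **Spatial patches** — median malignant pctMT in origin-anchored
  1000 × 1000 px patches (patches with <10 malignant cells excluded) and a
  Spearman check that pctMT is not confounded by total counts.
- **Synthetic cohorts** — `synth_config()` / `simulate_*()` generate every
  input with plantable ground-truth effects (compartment pctMT shifts,
  HighMT-coupled stress programs, MT excess, drug correlations, spatial
  regions), so the whole pipeline is testable offline.

All tabular results are tibbles; fitted objects have `tidy()`/`glance()`
methods and `autoplot()`/`plot_*()` figures.

## Worked example

```r
library(highmt)

cfg  <- synth_config(n_patients = 4, cells_per_patient = 300, seed = 7)
sim  <- simulate_cohort(cfg)          # cells + ground truth
qc   <- run_qc(sim$cells)             # pctMT-free quality control
cells <- add_pctmt(qc$filtered)       # pctMT + HighMT status per cell

annotate_case_control(patient_mt_summary(cells))
#> # A tibble: 4 x 10
#>   patient_id n_highmt_mal n_lowmt_mal n_highmt_tme n_lowmt_tme odds_ratio
#> 1 P01                  53          79            5         144      19.3
#> 2 P02                  34          88            2         145      28.0
#> 3 P03                  42          87           10         139       6.71
#> 4 P04                  42          84            6         144      12
#>   or_corrected highmt_malignant_fraction status exclusion_reason
#> 1 FALSE                            0.402 case   <NA>
#> 2 FALSE                            0.279 case   <NA>
#> 3 FALSE                            0.326 case   <NA>
#> 4 FALSE                            0.333 case   <NA>
```

Every patient here is a *case*: the generator plants a higher malignant MT
fraction (mean 15% vs 5% in the TME), so the malignant compartment is
enriched for HighMT cells (odds ratios 6.7–28) and more than 15% of
malignant cells are HighMT. Is that coupled to dissociation stress? Scoring
the stress program and correlating with HighMT status:

```r
norm   <- normalize_cp10k_log1p(cells)
stress <- score_signature(norm, sim$stress_signature, seed = 7)
mal    <- cells$cell_meta$compartment == "malignant"
point_biserial(stress$score[mal], cells$cell_meta$highmt[mal])
#> # A tibble: 1 x 4
#>        r t_stat p_value     n
#> 1 0.0295  0.664   0.507   509
```

With no planted stress coupling the point-biserial correlation is near zero
(r = 0.03, p = 0.51): HighMT status in this cohort is not explained by the
dissociation-stress program, which is the package's central diagnostic.

`run_pipeline(cfg)` chains all stages (QC → pctMT → scoring → metacells →
pathways → bulk comparison → drugs → spatial) and returns the result tables
plus a JSON-able run manifest recording config and seed.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the full synthetic pipeline from scratch with the given seed —
QC, patient case/control annotation, stress scoring, metacell labeling,
pathway deltas, the bulk-vs-bulkified residual tests, the drug-association
analysis with permutation calibration, and the spatial patch summary — and
writes the JSON report to `--out`.
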