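---
title: "Methods: identifying viable high-mitochondrial-content malignant cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: identifying viable high-mitochondrial-content malignant cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Standard single-cell RNA-seq quality control removes cells with a high
percentage of mitochondrial RNA counts (pctMT), typically above 10–20%,
because high pctMT is a classic marker of membrane damage and dissociation
stress in healthy tissue. Malignant cells, however, frequently carry
genuinely elevated mitochondrial expression — through increased mtDNA copy
number, mitochondrial fission, or horizontal mitochondria transfer — so a
blanket pctMT filter risks deleting a viable and clinically relevant tumor
subpopulation. `highmt` provides the statistical machinery to (a) run QC
that never consults mitochondrial identity, (b) quantify per-patient
enrichment of HighMT cells in the malignant compartment, (c) ask whether
HighMT status is explained by dissociation stress, and (d) characterize what
is biologically different about HighMT cells (pathways, drug response,
spatial organization).

## Definitions and core model

* **pctMT** = 100 × (counts in detected MT genes) / (total counts), per
  cell. MT genes are designated by an explicit gene list or, by default, the
  `MT-` identifier prefix; an explicit list wins. Gene matching is exact and
  case-sensitive. Datasets differ in whether MT tRNA/rRNA genes are present;
  because nobody has shown results to be insensitive to this, the
  designation is configuration, not a constant.
* **HighMT**: pctMT strictly greater than the threshold (default 15%, the
  center of the 10–20% range used across published filters). A cell at
  exactly 15% is LowMT.
* **Patient odds ratio**:
  `OR = (n(HighMT,mal)/n(LowMT,mal)) / (n(HighMT,TME)/n(LowMT,TME))`.
  If any cell of the 2×2 is zero, 0.5 is added to all four entries
  (Haldane–Anscombe) and the result is flagged `or_corrected`, so users can
  exclude corrected patients if they prefer.
* **Case**: OR strictly greater than 2 *and* HighMT fraction in the
  malignant compartment at least 0.15 (inclusive — "at least 15%" is taken
  literally, in contrast to the strict OR cutoff). Patients with fewer than
  30 cells in either compartment, or fewer than 20 HighMT cells in total,
  are excluded with an explicit reason rather than silently dropped.
* **Normalization** is counts-per-10k followed by natural `log(1 + x)`
  everywhere; it is invariant to per-cell scaling of raw counts and keeps
  zeros zero.

## Quality control without pctMT

Three per-cell metrics are computed per patient: `log1p` total counts,
`log1p` genes detected, and the fraction of counts in the cell's 50 most
expressed genes. A cell is flagged when any metric deviates from the patient
median by more than 5 *raw* (unscaled) median absolute deviations — the
convention of the best-practice guideline this mirrors; applying the 1.4826
normal-consistency factor would silently change what "5 MADs" means.
Absolute bounds (<1500 counts, >50,000 counts, <500 genes; all strict) and
an optional input doublet flag complete the filter. All flags are computed
in one pass on the input table — the original description does not say
whether the metrics were applied jointly or iteratively, and one-pass OR-ing
is the reproducible choice: flags commute and the removal set equals the
union of the individual flag sets. MALAT1-style diagnostics are a report
(`gene_qc_summary()`), not a filter, since only distribution comparisons are
ever made with them.

The traditional threshold filter (`pctmt_threshold_filter()`, removing
pctMT > 15%) exists solely so `compare_filtering_strategies()` can
demonstrate what it destroys.

## Signature scoring

`score_signature()` implements bin-controlled scoring: genes are ranked by
mean expression over the scored observations (not an external reference) and
cut into `n_bins = 25` equal-size bins; each signature gene is paired with
control genes from its own bin, and the score is the mean signature
expression minus the mean of the per-gene control means. One deliberate
refinement: when a gene's bin holds at most `ctrl_size = 50` genes, the
*whole bin* is used as its control deterministically; sampling (with
replacement, seeded) only kicks in for larger bins. This keeps the scorer's
degenerate case exact — a signature containing every gene scores identically
zero, because the bin-size-weighted average of bin means is the global mean.
Scoring parameters are recorded on the result and in the run manifest; the
original analyses name the tool but not its parameters, so the tool's
defaults are used and surfaced.

Because the score is relative to bin-mates, removing a cell population
(e.g. by threshold filtering) recenters the remaining scores; comparisons
between filtering strategies therefore look at whole score distributions
(Mann–Whitney) and tail behavior, not at absolute means.

The dissociation-stress meta-signature is the exact intersection of
independently derived stress signatures (`build_meta_signature()`, requiring
at least two sets). Association between a score and HighMT status is the
point-biserial correlation — Pearson against the 0/1 indicator with t-based
significance on n − 2 degrees of freedom.

## Metacells

Per-cell scores are noisy and statistically non-independent within patients;
aggregating ~25 same-type cells into disjoint metacells reduces both
problems. The published metacell algorithms use graph partitions; their
downstream statistics, however, depend only on the contract — disjoint,
homogeneous, roughly fixed-size groups with conserved counts — so `highmt`
uses a transparent surrogate: within each (patient, cell type) stratum, PCA
on log1p-CP10K (top 30 components) followed by k-means with
`k = ceiling(n / 25)`. Strata smaller than the target form one metacell;
k-means degeneracy (indistinguishable cells) falls back to even chunking.
Counts are summed, so per-gene totals are conserved exactly. Stratifying by
patient avoids cross-patient chimeric metacells; whether the original
analyses pooled patients within cell types is unclear, so pooling is
available via `by_patient = FALSE`. Metacell labels use strict fractions:
HighMT if >30% of members are HighMT, malignant if >50% are malignant.

## Bulk versus bulkified

Bulk RNA-seq involves no tissue dissociation, so if HighMT cells were a
dissociation artifact, single-cell ("bulkified") MT expression should exceed
what paired bulk data predicts. Bulkification is `log1p(Σ counts)` per gene
for UMI data and mean per-cell TPM for full-length protocols. The
bulk→bulkified relationship is modeled by polynomial regression with degree
selected at the elbow of the R² curve: the smallest degree whose next step
improves R² by less than 0.01, else degree 6. Orthogonal polynomial bases
keep R² provably non-decreasing in degree. A caveat the tests document: a
forward elbow rule reads the R² *increments*, so a polynomial whose
lower-order projections vanish (e.g. a pure odd cubic on a symmetric design)
is invisible to it — degree recovery is guaranteed only when every order up
to the true degree contributes variance.

The statistic is the mean residual of MT genes under a model trained on
non-MT genes only. Its null is empirical: B = 500 draws of |MT| genes from
the 500 most expressed genes (ranked by bulkified expression — the original
does not say which side; this is configurable), each time refitting without
the drawn genes and recording their mean residual. The one-sided p-value
uses the +1 finite-sample correction, `(1 + #{null ≥ obs})/(B + 1)`, which
guarantees validity and `p ≥ 1/(B+1)`. The null set size equals the number
of MT genes because the statistic's sampling variance depends on it. The
top-expressed pool matters: MT genes sit at the very top of the expression
range, where measurement noise on the bulk side attenuates the fitted slope
and biases *any* top gene's residual upward — comparing MT genes against
random top-expressed genes absorbs most of that bias, though mildly
anti-conservative behavior remains possible when MT genes outrank the whole
pool. Both Bonferroni (default, per the source's figure captions) and BH
correction are offered; the source text is internally inconsistent about
which was used, so neither is endorsed.

## Pathways and xenobiotic metabolism

Each pathway is scored on malignant metacells per study and summarized by
the HighMT−LowMT median score difference; pathways are ordered by their
median delta across studies, and the delta vectors are clustered with Ward
linkage (`ward.D2`) on Euclidean distances (rows with missing deltas are
dropped by default). Binning for control genes is per study — pooled binning
would let a deep study dominate the expression ranking of a shallow one. The
xenobiotic comparison scores the three phases (CYP oxidation, UGT/GST
conjugation, ABC efflux) and tests HighMT vs LowMT malignant metacells with
a two-sided Mann–Whitney per phase per study.

## Drug association

For every (drug, cancer type) with at least 3 cell lines and non-constant
values, Pearson's r between pctMT and IC50 is computed with
`t = r sqrt((n−2)/(1−r²))` significance; degenerate pairs are retained with
an exclusion reason. Per-drug medians across types define the top/bottom 15
(resistance/sensitivity tails; ties broken lexicographically and flagged).
Category enrichment uses the sample cross-product odds ratio with the
two-sided Fisher exact p-value. IC50 is used on the scale provided (a log
transform is a flag, not a default, since none is stated by the source).
The permutation calibration permutes pctMT across cell lines *within* each
cancer type — preserving type composition; the original's permutation scheme
is unspecified, so this choice is prominent and documented — and compares
the 5th/95th percentiles of the per-drug median-r distribution against their
permutation nulls with +1-corrected one-sided p-values.

## Spatial patches

Cells (or segmented spots — the analysis operates on whatever units the
input rows represent) are binned into an origin-anchored grid of
1000 × 1000 px half-open patches `[k·p, (k+1)·p)`; each patch is summarized
by the median pctMT over its malignant cells, and patches with fewer than 10
malignant cells are marked excluded. Grid alignment is a stated convention
(the source gives none). The confounder check is Spearman's rank correlation
between pctMT and total counts per compartment — rank-based by choice since
no coefficient is named; Pearson is available.

## The synthetic world

The generator's job is to make every planted effect recoverable by the stage
that should recover it. Its defaults describe a desk-scale cancer cohort:

* 8 patients × 400 cells, 1000 genes of which 13 are mitochondrial
  (mirroring the 13 protein-coding MT genes), 50% malignant.
* The MT fraction is modeled *at the probability level*: each cell draws a
  true fraction f from a per-compartment Beta law (malignant mean 0.15,
  κ = 10; TME mean 0.05, κ = 20 — centered on the HighMT threshold for the
  malignant compartment, well below it for the TME, with realistic spread)
  and MT genes receive total multinomial weight exactly f. Measured pctMT is
  therefore a noisy, unbiased estimate of 100f, matching the estimator the
  pipeline computes.
* Totals are log-normal (median 6000, σ_log 0.35); a 5% junk fraction
  (totals ~400, counts concentrated on 15 genes) gives QC something to
  remove. Per-cell mean-1 Gamma jitter (shape 3) on gene weights emulates
  biological expression variability; without it the cohort is so
  homogeneous that the 5-MAD top-50 filter degenerates into a surrogate
  pctMT filter, which no real dataset shows.
* Program effects (stress, pathway shifts) multiply gene weights within the
  non-MT block only and the block is renormalized, so planting a program
  never changes a cell's true MT fraction.
* Bulk pairs: bulk = monotone polynomial of the bulkified value plus
  Gaussian noise (sd 0.15); a patient's MT excess is planted by deflating
  the bulk-side MT values by log(excess), i.e. the single-cell side exceeds
  the bulk-based prediction by exactly that factor.
* Drug panels: cell-line pctMT per cancer type (type-level median pctMT
  drawn between 4% and 14%, the range observed across cancer-type panels),
  and per-drug IC50 as a linear blend of standardized pctMT and noise so the
  within-type Pearson correlation converges to the configured true r.
* Spatial fields: uniform cell placement with region-specific malignant
  pctMT means (default 20% vs 5% halves) and totals independent of pctMT.

What the generator does *not* emulate — gene–gene covariance, batch
effects, ambient RNA, dropout structure beyond multinomial sampling — bounds
what a green test establishes: the pipeline recovers its planted effects
under multinomial noise with realistic per-cell variability, not that it is
robust to every artifact of real droplet data.

## Numerical choices

* All thresholds follow the stated conventions: strict `>` for HighMT, OR
  and metacell label cutoffs; inclusive `≥` for the case fraction criterion;
  strict `<`/`>` for the absolute QC bounds.
* Unscaled MAD, two-sided, per patient.
* Resampling p-values always carry the +1 correction; every stochastic
  routine takes a seed and is bit-reproducible given it.
* Ward clustering relies on `stats::hclust(method = "ward.D2")`; the test
  suite checks it against an independent Lance–Williams implementation.
* Tie-breaks (max-score label assignment, drug rankings) are lexicographic
  and flagged.
* The all-genes scoring identity holds exactly when every bin is at most
  `ctrl_size` genes (i.e. up to `n_bins × ctrl_size` genes); beyond that the
  sampled-control path applies and the identity holds in expectation.

## Known limitations

* The metacell surrogate does not reject outlier cells within a stratum and
  does not optimize partition quality beyond k-means; purity on strongly
  separated populations is tested, subtle substructure is not.
* The elbow degree-selection rule cannot see polynomial terms whose
  lower-order projections vanish (see above).
* The permutation scheme for the drug calibration and the statistic it
  compares (tail quantiles of the median-r distribution) are documented
  stand-ins for an unspecified original.
* Compartment labels (malignant/TME) and doublet flags are inputs; copy
  number inference and doublet detection are out of scope.
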