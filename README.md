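# glycostrat

Glycolysis-based stratification of pancreatic ductal adenocarcinoma (PDAC)
transcriptomes.

PDAC tumors differ sharply in how strongly their tumor cells engage
glycolysis, and that metabolic axis tracks clinically meaningful structure:
interpatient heterogeneity in single-cell embeddings, molecular subtype,
hypoxia, and overall survival. `glycostrat` packages that analysis as
tested, reusable components for bulk and single-cell expression data,
together with synthetic-data generators so every stage can be exercised and
calibrated without access to patient cohorts.

## What it computes

**Glycolytic score and groups.** For a normalized genes × samples matrix
*X* and the 14-gene glycolytic signature *G* = {HK1, HK2, PGAM4, LDHA,
SLC2A1, PKM, ALDOA, ENO1, ALDOC, GPI, PGAM1, GAPDH, TPI1, PKLR}, the score
of sample *j* is the mean expression of the signature genes,

&nbsp;&nbsp;&nbsp;&nbsp;s<sub>j</sub> = (1/|G|) Σ<sub>g∈G</sub> X<sub>gj</sub>.

Single-cell cohorts are split at the cohort median (strictly exceeding the
median ⇒ High, otherwise Low); bulk cohorts are split into
Low/Intermediate/High at the 1/3 and 2/3 quantiles of the score
distribution.

**Interpatient heterogeneity.** Given a k-dimensional embedding (e.g. UMAP)
of tumor ductal cells, per-patient centroids c<sub>i</sub> are the mean
coordinates of each patient's cells, and the heterogeneity statistic is the
mean pairwise Euclidean distance

&nbsp;&nbsp;&nbsp;&nbsp;D = mean<sub>i&lt;j</sub> ‖c<sub>i</sub> − c<sub>j</sub>‖.

Significance comes from a permutation test: patient labels are uniformly
shuffled across cells n<sub>perm</sub> = 1000 times, the statistic is
recomputed each time, and the empirical p-value is the fraction of shuffled
statistics ≥ the observed one.

**Companion stratifiers.** Hypoxia signature = intersection of
tumor-upregulated genes with HIF-1α transcriptional targets, scored as the
per-sample median; basal-like vs classical subtype = argmax of the two
signature means; tumor purity binned <50 / 50–75 / >75 percent.

**Cohort statistics.** Group × covariate contingency tables tested with
chi-square and Fisher's exact test (Fisher primary when any expected count
< 5, or for 2×2 tables with n < 40), p-values reported to four decimals and
ranked; Benjamini–Hochberg adjustment; Kaplan–Meier 3-year overall survival
with administrative censoring at 36 months, the log-rank test, and a Cox
proportional-hazards trend test across the ordered groups.

**Spatial QC.** A region-of-interest filter applying seven strict sequencing
thresholds (reads > 1000; > 80% of reads trimmed, stitched and aligned;
saturation > 50%; minimum negative-control counts > 5; no-template-control
counts < 3000; > 100 nuclei; area > 1000 μm²).

## Worked example

The `analysis/` directory chains the full workflow on synthetic data;
`Rscript analysis/01_simulate.R` through `05_roi_qc.R` run in order. The
core steps, interactively:

```r
library(glycostrat)

# a cohort of 10 patients x 100 tumor cells with a strong patient effect
cfg <- sim_config(n_patients = 10, cells_per_patient = 100,
                  between_sd = 5, within_sd = 0.5, glyco_shift = 3,
                  seed = 20260927)
sim <- gen_single_cell(cfg)

# glycolytic score per cell, averaged per patient, median split
sc  <- signature_score(sim$expr, glycolytic_signature())
by_patient <- tapply(sc$scores, sim$cells$patient_id, mean)
stratify_by_median(score_vector(names(by_patient), as.vector(by_patient)))
#> <group_assignment> scheme 'median_2group', 10 samples
#>  Low High
#>    5    5

# interpatient heterogeneity in the embedding
permutation_test(sim$cells, n_perm = 1000, seed = 20260927)
#> <permutation_result> observed = 7.5768, p = 0 (n_perm = 1000, seed = 20260927)
#>   null: mean 0.6922, range [0.3462, 1.1047]; p_plus_one = 0.000999
```

The observed mean intercentroid distance (7.58) is an order of magnitude
above the shuffled-label null (mean 0.69); no shuffle reaches it, so the
empirical p is 0, i.e. p < 0.001 at 1000 permutations — patients occupy
genuinely separated territories of the embedding. The median split recovers
the 5 planted high-glycolysis patients exactly.

On the bulk side, a 300-sample cohort with a planted High-vs-Low hazard
ratio of 3 (`gen_cohort`) gives, via `km_fit(cohort, horizon = 36)`,
36-month survival of 0.38 / 0.10 / 0.03 for Low / Intermediate / High,
log-rank p = 5.7e-12 and Cox trend p = 7.0e-13, while the independently
drawn covariates stay null in `rank_associations` (all primary p > 0.05).

## Package layout

- `R/` — simulators (`gen_embedding`, `gen_single_cell`, `gen_cohort`),
  scoring and stratification (`signature_score`, `stratify_by_median`,
  `stratify_by_tertiles`, `build_hypoxia_signature`, `hypoxia_score`,
  `call_subtype`, `bin_purity`), heterogeneity (`centroids`,
  `mean_intercentroid_distance`, `permutation_test`), cohort statistics
  (`contingency`, `association_test`, `rank_associations`, `bh_adjust`,
  `km_fit`), I/O and QC (`read_gmt`, `read_expression`, `roi_qc_filter`,
  `run_pipeline`).
- `analysis/` — numbered narrative drivers over those functions.
- `inst/extdata/` — the packaged 14-gene signature (GMT), a symbol alias
  table, and small synthetic example gene sets (files labelled
  `_synthetic`).
- `vignettes/glycolytic-stratification.Rmd` — the methods vignette.
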