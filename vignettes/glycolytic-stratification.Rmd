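---
title: "Glycolysis-based stratification of PDAC: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Glycolysis-based stratification of PDAC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycostrat)
```

Pancreatic ductal adenocarcinoma (PDAC) tumor cells vary widely in how
strongly they express the glycolytic program, and that variation is
patient-structured: in integrated single-cell embeddings, each patient's
tumor ductal cells tend to occupy their own territory. `glycostrat`
implements the quantitative skeleton of a glycolysis-centred stratification
analysis — scoring, group assignment, a permutation test of interpatient
heterogeneity, hypoxia and subtype calling, association testing, and
3-year survival endpoints — with synthetic generators that make every stage
testable and calibratable. This vignette explains the models, the
parameters that matter, and the choices made where conventions were open.

## The glycolytic score and its stratifiers

The score of a sample (or cell) is the arithmetic mean of its normalized
expression over the 14-gene glycolytic signature (HK1, HK2, PGAM4, LDHA,
SLC2A1, PKM, ALDOA, ENO1, ALDOC, GPI, PGAM1, GAPDH, TPI1, PKLR). Two
details are deliberate:

- **Symbol reconciliation** is case-insensitive after trimming, with a small
  packaged alias table. The signature circulates in two spellings of the
  pyruvate kinase gene — PKM2 in bulk-cohort lists, PKM in cell-line
  resources — which name the same locus, so PKM2 is aliased to PKM.
- **Missing genes are reported, never imputed.** A signature whose coverage
  in the matrix falls below `min_fraction` (default 0.5) is an error that
  lists the missing symbols; any missing gene at all produces a warning.
  Averaging over present genes only keeps the score comparable across
  platforms at the cost of a small composition shift, which the
  `genes_missing` field makes visible.

Two stratifiers consume the score. The **median split** labels a sample
High only when its score *strictly exceeds* the cohort median — a literal
reading of "exceeded the median" — so ties at the median go Low, and a
constant cohort is all-Low rather than arbitrarily split. The **tertile
split** cuts at the 1/3 and 2/3 quantiles using the linear-interpolation
quantile estimator (R's default type 7); bins are lower-open/upper-closed
(score ≤ q₁⁄₃ → Low; q₁⁄₃ < score ≤ q₂⁄₃ → Intermediate; above → High). No
estimator was mandated by convention, so the common default was chosen and
the thresholds are stored on the result for audit. Both stratifiers are
rank-determined: any strictly monotone transformation of the scores leaves
the labels unchanged (a property the test suite checks).

The companion stratifiers follow the same pattern of explicit, documented
tie and boundary rules: the per-sample **hypoxia score** is the median of
the hypoxia-signature genes (even counts: midpoint of the two central order
statistics), the signature itself being the symbol-normalized intersection
of tumor-upregulated genes with HIF-1α targets (empty intersection is an
error, not an empty signature); **subtype** is the argmax of the basal-like
and classical signature means with exact ties going to Classical under a
warning (ties are measure-zero on continuous data); **purity bins** place
both 50 and 75 in the middle bin so that <50 / 50–75 / >75 is exhaustive
and disjoint.

## The heterogeneity statistic and its permutation null

For an embedding with per-cell patient labels, per-patient centroids are
the mean coordinates of each patient's cells and the heterogeneity
statistic D is the mean of all pairwise Euclidean centroid distances. The
null model shuffles the patient labels uniformly across cells — globally,
not stratified by cell type — leaving coordinates fixed, and recomputes D;
the empirical p is the fraction of the 1000 shuffled statistics ≥ observed.

Choices worth knowing:

- **p may be exactly 0.** The "fraction ≥ observed" definition is kept
  verbatim; the conventional (b+1)/(n_perm+1) estimate, which is never 0,
  is reported alongside as `p_plus_one`.
- **Ties count toward rejection.** A shuffle reproducing the observed
  statistic counts in the numerator. To make this exact in floating point,
  the observed statistic is computed through the identical `rowsum`
  arithmetic as the shuffled ones, so a permutation that happens to
  recreate the original bipartition ties the observed value bit-for-bit.
  The exhaustive-enumeration oracle test (all label arrangements of ≤ 8
  cells) would catch any drift here.
- **One seeded generator drives all shuffles sequentially**, so a
  (data, seed) pair replays exactly.
- The statistic is dimension-agnostic (any k ≥ 1), although 2-D UMAP is the
  typical input. No per-patient subsampling is applied before centroid
  computation.

## Survival and association endpoints

The 3-year overall-survival endpoint **administratively censors** all
follow-up beyond 36 months — subjects with later events become censored at
36 — then fits per-group Kaplan–Meier curves, the unweighted log-rank test,
and, when the three ordered groups are present, a Cox proportional-hazards
score test on the integer-coded group (Low = 0, Intermediate = 1,
High = 2) as the trend test. Censoring-at-horizon was chosen over merely
truncating the plotted axis because it makes "3-year survival" a
well-defined estimand; with zero events the curves are returned flat at 1
and the tests are reported absent rather than fabricated.

Association testing computes both chi-square (continuity-corrected for
2×2) and Fisher's exact test, keeping both p-values, and designates a
primary one by the Cochran-style rule: Fisher when any expected count is
below 5 or for a 2×2 table with n < 40, chi-square otherwise. For larger
than 2×2 tables Fisher is attempted only when an expected count is small
and n ≤ 500, the practical bound of the exact network algorithm. The
primary p is rounded to four decimals for reporting, with full precision
retained in `p_exact` so downstream ranking is not quantized. Note that
Fisher and chi-square p-values genuinely diverge (by up to ~0.09) at
mid-range p even on large tables with ample expected counts; they agree
closely only where the decision is clear-cut, which is what the test suite
asserts. Benjamini–Hochberg adjustment is exposed as a thin, validated
wrapper over the standard step-up procedure.

## What the synthetic generators emulate

`gen_embedding` draws patient centroids i.i.d. from a spherical normal with
sd `between_sd` and scatters each patient's cells around its centroid with
sd `within_sd`. The defaults — 10 patients × 100 cells, `between_sd = 5`,
`within_sd = 0.5` — describe the strongly patient-separated regime in which
the heterogeneity test should reject decisively; setting `between_sd = 0`
makes cells exchangeable and provides the calibration null. For two
patients the intercentroid distance has mean `between_sd`·√π (the norm of a
N(0, 2σ²I₂) difference is Rayleigh), which the tests verify by simulation.

`gen_single_cell` lays log-normal expression noise (normal on the log
scale, baseline 1, sd `noise_sd = 0.5`) over a gene universe containing the
signature, and adds `glyco_shift` (default 3, i.e. six noise sd) to the
signature genes of the floor(n/2) lowest-index patients, which are the
ground-truth "high" patients. The deterministic truth map supports exact
label-recovery tests. Log-normal noise was chosen over negative-binomial
counts because every downstream operation consumes normalized values; the
distributional shape is scaffolding, not a claim about real scRNA-seq data.
Consequently, passing recovery tests demonstrate the pipeline's logic, not
robustness to count overdispersion, dropout, batch effects or ambient
contamination, none of which are simulated.

`gen_cohort` gives each of `n_samples = 300` samples a standard-normal
glycolytic score, assigns tertile groups, and draws exponential survival
times with hazard `baseline_hazard = 0.03`/month for Low, multiplied by
`hazard_ratio_high_vs_low = 3` for High and by its square root for
Intermediate (a log-linear gradient, so the trend test has a well-defined
target), administratively censored at 36 months. Baseline 0.03/month puts
Low-group median survival near 23 months — a realistic order of magnitude
for advanced PDAC — and leaves roughly 250 of 300 subjects with observed
events at the horizon, enough for stable log-rank and Cox estimates.
Covariates (KRAS mutant 70%, stage T3 50%, basal-like 35%, purity uniform
on 20–95%) are drawn independently of the group with their marginals
recorded on the output: they are association-test scaffolding with null
truth, not a generative model of PDAC biology.

Seeding: each generator call consumes one seed; internal sub-streams are
derived by fixed offsets, so identical (config, seed) pairs give
bit-identical outputs without coupling between generators.

## Problem sizes and numerical choices

The test suite and the analysis scripts run the heterogeneity test at
10 × 100 cells with 1000 permutations (seconds), calibration at 200
replicates of 100 permutations each, label recovery over 50 seeds, and
hazard-ratio recovery over 100 seeds at n = 300 — sizes chosen to make the
stochastic properties sharp (binomial 99% intervals, ±30% recovery bands)
while keeping a full run in the tens of seconds. Degenerate inputs are
handled by explicit policy rather than silence: zero-sum library columns,
single-group embeddings, all-tied scores, empty gene-set intersections and
zero-event cohorts each produce a defined result or a named error, as
documented on each function.

## Known limitations

- Embeddings are inputs; the package does not compute UMAP or assess
  integration quality beyond the centroid statistic.
- Purity values, upregulated-gene lists and HIF-target lists are inputs;
  no differential-expression engine, enrichment analysis or purity
  inference is reimplemented.
- The synthetic generators model none of: count-level noise, spatial probe
  chemistry, batch structure, or covariate–outcome coupling. Claims
  validated on them transfer to real cohorts only insofar as the real data
  meet the stated assumptions (normalized expression, exchangeable cells
  under the null, proportional hazards).
- The permutation test is one-sided (≥ observed) by construction; no
  two-sided variant is offered.
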