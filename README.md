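# mycstrat

Stratification of pancreatic tumor and cell-line transcriptomes by MYC
activity, and the statistics linking that activity to drug vulnerability.

A minority of pancreatic ductal adenocarcinomas (PDAC) show coordinate
activation of MYC target genes. This subtype matters clinically: it is
associated with squamous/basal-like histology, worse survival, and increased
sensitivity to drugs that perturb protein homeostasis (notably the
proteasome inhibitor bortezomib). mycstrat packages that analysis workflow
for R users:

- **Consensus MYC classification** — per-signature hierarchical clustering
  (Euclidean distance, Ward linkage on row-scaled expression) with the
  "common MYC-high" call defined as the intersection of high calls across a
  panel of MYC target signatures.
- **Gene set enrichment analysis** — a from-scratch engine for the weighted
  Kolmogorov–Smirnov running-sum statistic
  `ES = max deviation of (P_hit - P_miss)`, with signal-to-noise gene
  ranking, phenotype or gene-set permutation null, `NES = ES / mean |ES_null|`
  (sign-matched), add-one smoothed nominal p, and tail-ratio FDR q-values;
  plus cross-dataset intersection of enriched sets at an FDR threshold.
- **Drug-screen statistics** — the single-dose hit rule
  `ratio = mean response(MYC-high) / mean response(MYC-low) > 2` (response =
  100 − viability), four-parameter logistic dose-response fitting with
  relative and absolute GI50, normalized dose-response AUC,
  sensitivity-quartile phenotype construction, and GI50 cross-correlation.
- **Cohort statistics** — Kaplan–Meier estimation, the two-group log-rank
  test, an exact two-sided Fisher test by hypergeometric enumeration, and
  ΔΔCt qPCR quantification.
- **Synthetic data with planted truth** — generators for cohorts, screens
  and dose-response series carrying the exact structure the analysis
  assumes, so the full pipeline is testable end-to-end without external
  consortium data.

File formats: tab-delimited expression matrices, GCT #1.2, GMT gene-set
collections, CLS phenotypes, and drug-response TSVs, all with strict
validation and bit-exact TSV round-trips.

## Worked example

Simulate a cohort of 80 tumors in which 8 (10%) carry a 1.5-SD shift of the
MYC signature genes, classify it, and test signature enrichment in the
called subtype:

```r
library(mycstrat)

cohort <- simulate_cohort(cohort_sim_config(n_samples = 80, seed = 3))
calls  <- classify_myc(cohort$expression, cohort$signatures, k = 2)
calls
#> MycCallSet: 8 consensus-high of signatures [ MYC_SIG_1=8, MYC_SIG_2=8, MYC_SIG_3=8 ]

labels <- phenotype_labels(
  ifelse(colnames(cohort$expression) %in% calls$consensus_high, "MYC_high", "rest"),
  class_names = c("MYC_high", "rest"),
  sample_ids  = colnames(cohort$expression))
sets <- c(cohort$signatures,
          random_gene_sets(rownames(cohort$expression), 10, 50, seed = 9))
res <- gsea(cohort$expression, labels, sets, n_perm = 200, seed = 5)
head(res[, 1:6], 4)
#>         set size         es        nes   p_nominal     fdr_q
#> 1 MYC_SIG_1   50  0.9409682  2.5459794 0.009708738 0.0000000
#> 2 MYC_SIG_2   50  0.9281694  2.6288762 0.009803922 0.0000000
#> 3 MYC_SIG_3   50  0.9198794  2.5929983 0.009900990 0.0000000
#> 4 DECOY_001   50  0.2193573  0.8475295 0.760869565 0.6978691
```

All 8 truth-high samples are recovered by the consensus call, the three
planted signatures enrich in the called subtype with NES ≈ 2.5–2.6 and
FDR q = 0 at this permutation depth, while a random decoy set of the same
size sits at chance (p ≈ 0.76).

Score a synthetic 129-drug single-dose screen with 10 planted hits:

```r
truth <- c(H1 = TRUE, H2 = TRUE, L1 = FALSE, L2 = FALSE)   # 2 high, 2 low lines
sim <- simulate_screen(screen_sim_config(seed = 101), truth)
hits <- score_single_dose_screen(sim$table, sim$groups)
sum(hits$is_hit)
#> [1] 10
```

The ratio > 2 rule recovers exactly the ten planted hits.

`run_full_analysis(pipeline_config(seed = 1))` chains the whole workflow —
two cohorts, classification, per-cohort GSEA, cross-cohort intersection,
screen scoring, GI50 fitting and quartile enrichment, survival and subtype
association — into a single JSON report. A thin command-line wrapper lives
at `inst/cli/mycstrat`.

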