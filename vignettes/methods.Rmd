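---
title: "Methods: consensus MYC stratification and drug-vulnerability statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus MYC stratification and drug-vulnerability statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mycstrat)
```

## The problem

A minority of pancreatic ductal adenocarcinomas (PDAC) show coordinately
elevated expression of MYC target genes — a "MYC-hyperactive" subtype with
worse outcome, enrichment in the squamous/basal-like histology, and, the
therapeutically interesting part, increased sensitivity to perturbation of
protein homeostasis (proteasome inhibitors such as bortezomib). mycstrat
implements the computational side of that analysis as a reusable, tested
pipeline: calling MYC-high samples from transcriptomes, quantifying pathway
enrichment in the called subtype, linking MYC activity to drug response in
single-dose and multidose screens, and the supporting survival and
association statistics. Everything runs end-to-end on synthetic data with
planted structure, so each stage's behaviour is verifiable without access to
consortium datasets.

## Consensus MYC classification

`cluster_by_signature()` subsets the log2 expression matrix to the genes of
one MYC target signature, scales each gene row to zero mean and unit
variance, and clusters the samples by agglomerative hierarchical clustering
with Euclidean distance and Ward linkage. We use `ward.D2` — the Ward
criterion on squared Euclidean distances — which is what current
ClustVis-style pipelines and `hclust` compute; the choice is stated here
because the two Ward variants differ and ports must agree. Zero-variance
rows are dropped with a warning, and signature genes absent from the matrix
are dropped rather than imputed, which is what makes a human-derived
signature portable to murine data (with `case_fold = TRUE` on reading to
align `Myc` with `MYC`).

The tree is cut into `k` clusters. The high/low dichotomy implied by the
analysis makes `k = 2` the default; `k` is exposed because real cohorts can
fragment into more than two expression states. `call_high_cluster()` returns
the cluster with the largest mean row-scaled signature expression. The
optional `secondary_threshold` rule re-admits any additional cluster whose
mean scaled expression exceeds the threshold (conventionally 0): this is the
escape hatch for a cluster with *incomplete* but elevated target-gene
expression that belongs with the high group — something otherwise recognized
by eye on a heatmap. It is off by default so that the default path is fully
automatic and conservative.

A sample is **common MYC-high** when every signature in the panel calls it
high; `consensus_calls()` forms the intersection and emits per-signature and
Venn overlap counts. The consensus can be empty — that is a valid result
with a warning, not an error.

Exact ties between cluster means are broken toward the cluster containing
the lexicographically smallest sample ID, with a warning; this never matters
on continuous data but keeps degenerate fixtures deterministic.

## The enrichment engine

`gsea()` is a from-scratch implementation of the weighted Kolmogorov–Smirnov
running-sum statistic.

**Ranking.** Genes are ranked by signal-to-noise ratio between the two
phenotype classes: `(mu_pos - mu_neg) / (sd_pos + sd_neg)`, each class SD
floored at `max(0.2 * |mu|, 0.2)`. The floor prevents near-constant genes
from dominating the ranking; the constants are the convention of the
standard desktop tool, chosen so results are comparable with it. If a class
has fewer than two samples the metric degrades to a difference of means with
a warning. Ties are broken by gene ID ascending, so the ranking is stable
across platforms.

**Enrichment score.** Walking the ranked list, hits increment the running
sum by `|score|^p / sum_hits |score|^p` and misses decrement by
`1/(N - N_hit)`; the ES is the signed maximum deviation. `weight_p = 1` is
the weighted default, `p = 0` the classic unweighted statistic. When the
positive and negative extremes tie in magnitude — common in classic mode,
where the running sum takes rational values — the sign would otherwise
depend on floating-point summation order; we therefore let the positive
extreme win ties within 1e-12, in the user-facing walk, in the fast
permutation path, and in the test oracle. The permutation path computes the
ES only at hit positions (O(set size) per permutation); a property test
holds it equal to the full walk.

**Null and significance.** With `perm_type = "auto"` the engine permutes
phenotype labels when both classes have at least 7 samples and falls back to
gene-set resampling of equal size otherwise — the standard "depending on
sample size" guidance; both modes can be forced. The nominal p is the
fraction of same-signed null ES at least as extreme, with add-one smoothing
`(b+1)/(m+1)` so it is never zero. NES divides the ES by the mean absolute
null ES of matching sign. The FDR q is the tail-ratio estimate over the
pooled sign-normalized null, clamped to [0,1] and monotonized within each
sign by a BH-style step-up (a more extreme NES never receives a larger q).
`n_perm` defaults to 1000. Set-size filters default to 5–500: the canonical
tool uses 15–500, but the synthetic collections here include deliberately
small sets, and the floor of 5 keeps those testable; both bounds are
parameters.

For the unweighted path reported as adjusted p-values rather than
GSEA-style q-values, `adjust_pvalues()` exposes BH and BY. The exact scoring
of the external web tool this mirrors is not fully published, so the classic
`p = 0` statistic with BH/BY stands in; this is an approximation by design.

## Screen statistics

**Single-dose hit calling.** `score_single_dose_screen()` works in response
space, `response = 100 - viability` clamped at 0. The hit statistic is the
mean response of the MYC-high lines divided by the mean response of the
MYC-low lines, and a ratio above 2 is a hit. The response convention is
load-bearing: a twofold *response* ratio selects drugs the MYC-high lines
are more sensitive to, whereas a viability ratio would invert the rule.
When the denominator drops below `epsilon = 1` percentage point the ratio is
computed against epsilon and flagged unstable — screens contain inert drugs,
and an honest flag beats an unbounded ratio. Replicates are averaged per
well, missing wells excluded with their effective n.

**Dose-response fitting.** `fit_4pl()` fits
`v(d) = bottom + (top - bottom)/(1 + (d/gi50)^hill)` by Levenberg–Marquardt
with the midpoint parametrized as `log(gi50)`, bounds `bottom >= 0` and
`hill` in [0.1, 10], and a multi-start over Hill seeds (0.5, 1, 2); the best
residual sum of squares wins. Both midpoints are reported because "GI50 by
nonlinear regression" is ambiguous: the *relative* GI50 (curve inflection)
and the *absolute* GI50 (dose where the fitted curve crosses 50% of
control), the latter censored at the highest tested dose when the curve
never crosses. A perfectly flat series is returned as the exact constant
fit with the absolute GI50 censored, rather than as a numerical failure.
`dose_response_auc()` integrates viability/100 over log10 dose by the
trapezoid rule, normalized by the log-dose span, so the value lies in [0,1]
(1 = fully resistant) and is invariant to a common dose rescaling.

**Sensitivity quartiles.** `quartile_stratify()` splits a panel at the 25th
percentile of the metric, computed with the type-7 (linear interpolation)
quantile — stated explicitly because quantile conventions differ across
languages and the boundary decides membership. Ties at the boundary are
included in the sensitive set. The emitted two-class phenotype feeds
directly into `gsea()`, reproducing the sensitive-quartile-versus-rest
enrichment design.

## Survival and association statistics

`km_estimate()` is the product-limit estimator with the event-before-censor
tie convention (a sample censored at an event time still counts at risk at
that time). `logrank_test()` is the standard two-group 1-df statistic.
`fisher_exact()` enumerates the hypergeometric distribution over all tables
with the observed margins and sums the probabilities not exceeding the
observed table's — the probability-mass definition of the two-sided p, fixed
here (with a 1e-12 relative tolerance on the comparison) because competing
two-sided definitions exist. A degenerate margin returns p = 1 with a
warning. No continuity corrections are applied anywhere.
`delta_delta_ct()` implements relative qPCR quantification,
`fold = 2^-ddCt`, with the reference sample pinned at fold 1.

## The synthetic-data generator

`simulate_cohort()` plants exactly the structure the analysis assumes:
gene-wise Gaussian background (SD 1 on the log2 scale), a fixed 10% of
samples with all signature genes shifted up by 1.5 SD (the effect size at
which consensus classification should succeed but is not trivial), three
signatures of 50 genes sharing a 10-gene core (20% pairwise overlap,
mirroring the real overlap of MYC target lists), exponential survival with
hazard ratio 2 for the high group and administrative censoring at the 70th
percentile of the low-group event distribution (about 30% censoring, in
days), and a binary "squamous" label drawn at 0.75 in high versus 0.15 in
low samples. `simulate_screen()` plants hit drugs at a threefold response
ratio over a 20% baseline response with 10% replicate CV in triplicate;
`simulate_dose_response()` perturbs an exact 4PL curve with multiplicative
noise. All generators are pure functions of (config, seed).

What the generator does **not** emulate: real PDAC expression covariance
beyond the planted block (no correlated housekeeping structure, no batch
effects), count-level RNA-seq noise (the matrix is log-intensity scale),
non-proportional hazards, or dose-dependent noise in screens. Passing tests
therefore demonstrate that the algorithms recover structure of the assumed
form — not that real cohorts satisfy those assumptions.

## Problem sizes and numerical choices in the test suite

The suite exercises: consensus recovery over 20 seeded cohorts at the
default design (n = 80, 10% high, effect 1.5); exhaustive enrichment-score
enumeration for every proper subset of every list up to length 12 (8166
cases against an independent walking oracle, and `fgsea`'s statistic as an
external cross-check for the weighted mode); GSEA null calibration over 200
null cohorts at 200 permutations; an end-to-end planted-truth run with
n = 80 and n = 150 cohorts at 1000 permutations; 100 noisy dose-response
curves at 2% CV; log-rank size over 1000 null simulations at 40 per arm;
Fisher agreement with exhaustive enumeration over all 46,375 two-by-two
tables with total at most 30; and byte-identical report JSON under a
repeated seed. These sizes were chosen so the full suite completes in a few
minutes while keeping every stochastic assertion comfortably away from its
threshold.

Two power-related facts are worth stating plainly. First, at the default
cohort design the survival comparison is 8 versus 72 samples; with hazard
ratio 2 and ~30% censoring the log-rank noncentrality is about 2.5, putting
power near 0.4 — the suite asserts rejection well above the nominal 5% size
rather than a majority. Second, the FDR q of a genuinely enriched planted
signature is usually reported as 0 at 1000 permutations: the tail-ratio
estimator's resolution is bounded by the pooled null, and the add-one
smoothed nominal p (never 0) is the better-calibrated quantity for small
collections.

## Known limitations

- The classifier's `k` and the secondary-inclusion threshold are parameters,
  not estimates; no automatic model selection is attempted.
- The tail-ratio FDR is the GSEA convention, not a BH guarantee; for small
  collections it is coarse, and the pooled null couples the q-values of
  different sets.
- The 4PL fitter reports non-convergence honestly (`converged = FALSE` with
  parameters) but does not attempt profile-likelihood intervals.
- The CLI (`inst/cli/mycstrat`) is a thin wrapper for scripted use; the R
  functions are the primary interface.
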