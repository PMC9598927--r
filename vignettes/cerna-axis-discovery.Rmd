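---
title: "Mining and validating ceRNA regulatory axes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining and validating ceRNA regulatory axes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ceRNAxis)
library(dplyr)
```

## The model

Under the competing endogenous RNA (ceRNA) hypothesis, a long non-coding
RNA (lncRNA) acts as a molecular sponge for a miRNA: when the lncRNA is
abundant it sequesters the miRNA, relieving the repression of that
miRNA's mRNA targets. A (lncRNA, miRNA, mRNA) triple with this coupling
is an *axis* (or ceRNA module). In a two-group comparison — here,
carcinogen-transformed versus passage-matched control bronchial
epithelial cells — the sponge relationship leaves a characteristic sign
pattern in differential expression:

* **oncogenic axis**: lncRNA up, miRNA down, mRNA up;
* **tumor-suppressive axis**: lncRNA down, miRNA up, mRNA down.

ceRNAxis implements the discovery procedure as a pipeline of pure,
tabular operations:

1. **Differential expression** per RNA class: Welch's unequal-variance
   t test on log2 intensities, Benjamini–Hochberg FDR across the
   profile, and a direction call. A feature is `up`/`down` when it
   passes the significance rule (by default, p ≤ 0.05 **or**
   −log10 FDR ≥ 2.0 — the union, matching the profile-wide convention)
   and has |log2FC| ≥ 1, i.e. a linear two-fold change.
2. **Candidate matching**: a miRNA is an axis candidate for the
   oncogenic polarity when it is down-regulated and has at least one
   up-regulated lncRNA partner *and* one up-regulated mRNA partner in
   the supplied miRNA-target interaction tables, both partners with
   linear |FC| ≥ 2; the suppressive polarity is the exact mirror.
3. **Assembly and ranking**: each candidate's (lncRNA × mRNA) partner
   pairs expand into axes; the lncRNA two-fold gate is re-asserted, and
   axes are ranked by the mean of the three components' −log10 p.
4. **Enrichment and overlap**: hypergeometric over-representation of DE
   genes against user-supplied term tables, Venn region counting for up
   to three sets, and per-gene interaction/stemness partner counting.
5. **Clinical validation**: per-component Kaplan–Meier curves, log-rank
   test and Mantel–Haenszel hazard ratio between high/low expression
   groups, plus ROC/AUC with sensitivity, specificity and accuracy at
   the Youden-optimal threshold.

## What is computable and what is not

Two ingredients of published ceRNA studies are inherently not
reproducible from a code artifact: literature-based judgements of
"relevance to cancer" used to shortlist axes, and the internal state of
web services (target-prediction snapshots, enrichment back-ends,
stemness databases). ceRNAxis replaces the former with the deterministic
`rank_score` above (with `top_k` exposed; three per polarity is the
conventional choice), and models the latter as *input tables*: the
interaction, annotation and catalog files are data, not services. The
union of interaction sources is the default; `min_sources = k` requires
agreement of k databases instead.

## The synthetic generator

Because the original microarray profiles are not redistributable, the
package ships a seeded generator that emulates the *structure* of the
study inputs so every stage is testable against known ground truth:

* **Expression**: per-feature baseline ~ N(8, 1.5²) log2 intensity; a
  log2 fold change split symmetrically between the two group means
  (planted values for axis members, N(0, `background_fc_sd`²)
  otherwise); independent N(0, `noise_sd`²) noise per observation.
  Defaults: 50 features per class, 3 arrays per group (a typical
  two-group microarray design), `noise_sd` = 0.5,
  `background_fc_sd` = 0.25. `noise_sd = 0` is the noiseless limit in
  which recovery is exact — used by the recovery tests.
* **Planted axes**: six by default, three per polarity, |log2FC| 1.5–2.5
  so the two-fold gates are satisfiable; sign patterns enforced at
  construction.
* **Interactions**: all planted edges plus `decoy_edge_count` uniform
  decoys per table. Two decoy regimes exist because they answer
  different questions: `"non_axis"` (default) draws decoys from all
  non-axis (miRNA, partner) pairs — a decoy may then legitimately
  complete an extra triple that truly satisfies the sign rule;
  `"non_de"` confines decoys to non-planted features, the regime in
  which planted-axis precision and recall are exactly 1 at zero noise.
* **Clinical cohort**: the three components of an axis share a standard
  normal latent factor (signed by each component's direction) plus
  N(0, 0.5²) component noise, so sponge partners are strongly
  inter-correlated; tumor subjects are shifted by `auc_effect` × the
  common SD along each component's direction, giving the equal-variance
  binormal AUC Φ(d/√2); survival is exponential with log hazard
  `hazard_coef` × 1(above-median mRNA expression), with independent
  exponential censoring calibrated to a 20% overall rate (censoring is
  rarely reported in the source literature; 20% is typical of lung
  cohorts). Defaults `hazard_coef` = ±0.7 (hazard ratio ≈ 2, as commonly
  reported for prognostic lncRNAs) and `auc_effect` = 1.19
  (Φ(1.19/√2) ≈ 0.80, the middle of the 0.71–0.92 AUC range typical of
  single-gene lung-cancer biomarkers).

The generator reproduces the *statistical* structure only: independent
Gaussian array noise, no probe effects, no normalization artifacts, no
mechanistic miRNA kinetics (sponge coupling is encoded purely through
opposite-sign fold changes — the assembly rule uses direction and
interaction only, so nothing stronger is needed), and exponential
survival without competing risks. Passing tests therefore demonstrate
the correctness of the algorithms, not the behaviour of the pipeline on
real microarray data.

## A worked run

```{r pipeline, eval = FALSE}
res <- run_pipeline(pipeline_config(
  simulation = simulation_config(noise_sd = 0.3, seed = 11)
))
res$axes$oncogenic |> select(lncrna_id, mirna_id, mrna_id, rank_score)
res$clinical_reports$oncogenic
```

With the default six planted axes and moderate noise the six triples are
recovered, and each component validates clinically (log-rank p < 0.05,
AUC ≈ 0.8 with the planted d = 1.19). `autoplot()` methods draw the
volcano plot of a `de_table`, the KM curves of a `survival_fit()` and
the ROC curve of `roc_auc()`; `tidy()`/`glance()` give broom-style
access to every fitted object.

## Numerical and design choices

* **DE test**: vendor microarray pipelines rarely document their test;
  Welch's t on log2 intensities is the standard two-group choice when no
  replicate structure is modelled. Moderated (empirical-Bayes) variance
  estimation is deliberately out of scope. Degenerate variances follow
  explicit conventions: equal means with zero variance give p = 1, and
  unequal means with zero variance give p = 0 with a `degenerate` flag
  (the noiseless limit).
* **FDR**: Benjamini–Hochberg, the standard step-up procedure, applied
  across the full profile of one RNA class; for enrichment, within one
  annotation namespace at a time (GO branches are distinct
  multiple-testing families).
* **Fold-change scales**: the profile-wide gate is |log2FC| ≥ 1 and the
  axis gates are linear |FC| ≥ 2 — the same quantity on two scales; both
  are exposed as parameters because conventions differ between array
  vendors.
* **miRNA identifiers**: matched case-insensitively with the "hsa-"
  prefix stripped; the -5p/-3p arm suffix is biologically meaningful and
  preserved.
* **Dichotomization**: the high/low split for survival is at the median
  (ties to low) by default, with a quantile option; the cutpoint is
  recorded.
* **Hazard ratio**: the Mantel–Haenszel observed/expected estimate from
  the log-rank tabulation, with the CI exp(log HR ± 1.96·√(1/E₁+1/E₂)).
  It matches the log-rank framing of the validation; a Cox model is out
  of scope.
* **ROC**: AUC is the Mann–Whitney probability with ties counted ½
  (equal to the trapezoidal area); the operating point maximizes
  Youden's J with ties broken toward the lower threshold; accuracy is
  raw accuracy there; the p value against AUC = 0.5 uses the
  tie-corrected normal approximation of the Mann–Whitney statistic. The
  clinical report orients each marker so AUC ≥ 0.5 (`direction =
  "auto"`), as clinical ROC software does; the low-level `roc_auc()`
  default keeps the stated orientation so that
  AUC(s) + AUC(−s) = 1 holds.
* **Ranking ties** break by |log2FC| of the lncRNA and then
  lexicographically, making the output fully deterministic; hierarchical
  leaf order in the clustergram is made deterministic by lexicographic
  pre-sorting of samples.

## Problem sizes used in validation

The test-suite and the acceptance script validate on: exact recovery at
50 features/class, 6 arrays/group, zero noise, 200 non-DE decoy edges;
brute-force equivalence on 100 random instances of ≤ 8 features/class;
null calibration on 500 null features (DE) and 500 null cohorts of 60
subjects (log-rank, hazard ratio, AUC); and the binormal AUC law at 500
subjects/class. These sizes give Monte-Carlo standard errors small
enough that the nominal 5% levels and the Φ(d/√2) law are sharp checks
while keeping a full run in the order of a minute.

## Known limitations

Real arrays violate the independence and homoscedasticity the generator
assumes; printed DE counts from any specific study additionally depend
on that study's (usually undocumented) vendor test statistic and on
un-versioned interaction-database snapshots, so they are not
reproduction targets. Candidate counts depend on whether target
databases are unioned or intersected (`min_sources`). The clinical layer
performs single-gene, component-wise validation — no multivariate Cox,
no time-dependent ROC, no pooling across the three components of a
module.
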