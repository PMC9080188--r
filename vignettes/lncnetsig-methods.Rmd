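---
title: "Methods: co-expression networks, survival screening and risk signatures for lncRNAs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-expression networks, survival screening and risk signatures for lncRNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncnetsig)
```

## The analysis in one paragraph

Long non-coding RNAs are rarely annotated, so their function in a tumor type
is usually inferred *by company*: a lncRNA that is differentially expressed
between tumor and normal tissue **and** tightly co-expressed with many mRNAs
is a plausible regulator, and its biology can be read off its mRNA
neighbors. `lncnetsig` implements that inference chain end to end:
differential expression filters candidate RNAs; a Pearson co-expression
network over the candidates defines hubs and modules; per-lncRNA survival
screening and a multivariate Cox risk signature connect network lncRNAs to
patient outcome; and a lncRNA → mRNA → GO term → cancer-hallmark chart
propagates functional annotation to the un-annotated lncRNAs. A
synthetic-data generator with planted ground truth makes every stage
testable by parameter recovery.

## Stage models and their assumptions

### Differential expression

Input matrices are abundance-scale (RSEM/RPKM-like); `preprocess()` removes
genes that are zero in every sample and applies `log2(x + pseudocount)`.
The pseudocount defaults to 1 (zeros map to 0); it is exposed because the
choice is a convention, not a fact of the data.

On the log2 scale, `differential_expression()` computes per-gene
`logFC = mean(tumor) − mean(normal)` and a two-sided Welch t-test, with
Benjamini–Hochberg FDR across genes (`bh_adjust()` wraps
`stats::p.adjust`). The candidate gate is `fdr < 0.05` and `|logFC| > 2`,
both strict. A count-model engine (edgeR-style TMM + negative-binomial
dispersion) is deliberately out of scope: the synthetic data and all
downstream computation live on the log2 scale, where a location test is the
appropriate default, and an externally computed DE table can be imported
with `read_de_table()` in the same schema. The gate can alternatively be
applied to the raw p-value (`gate_on = "p"`), since both conventions appear
in practice; FDR is the package default.

A gene with zero variance in both groups has no defined t statistic; it is
assigned p = 1 and flagged `degenerate` rather than dropped, so table
shapes stay predictable.

### Co-expression network

`build_network()` computes the Pearson correlation of every unordered
candidate pair over all samples (tumor + normal) and keeps edges with
`r > 0.85` and `p < 0.05`, both strict, where p comes from the t transform
`t = r√(n−2)/√(1−r²)`. Defaults follow the signed-threshold convention
(only positive co-expression forms edges); `use_abs = TRUE` admits negative
co-regulation. Using all samples (rather than tumor only) reflects the edge
rationale — pairs that move together across the full range of disease
states — and `sample_set = "tumor"` is available. No multiple-testing
correction is applied to edge p-values; at n ≈ 314 the r > 0.85 gate is the
binding constraint by many orders of magnitude, but the caveat stands for
small cohorts. Zero-degree nodes are pruned and modules are the connected
components, labelled deterministically (decreasing size, then smallest
member id).

### Topology

Degree and Brandes betweenness (via igraph) rank hubs;
`fit_power_law()` characterizes the degree distribution by least squares on
(log k, log frequency) — the descriptive convention for small biological
networks. Maximum-likelihood (Clauset-style) tail fitting is a non-goal at
~100 nodes.

### Survival statistics

All survival primitives are implemented in the package and cross-checked in
the test suite against the `survival` package and brute-force oracles:

* `km_estimate()` — product-limit estimator.
* `logrank_test()` — k-group log-rank with hypergeometric variance.
* `optimal_cutpoint()` — maximally selected rank statistic: the marker is
  scanned over all cutpoints leaving at least `minprop = 0.1` of patients
  on each side, and the split maximizing the absolute standardized log-rank
  statistic is returned. The statistic is computed in log-rank *score* form
  (martingale-residual scores with permutation variance), which is exactly
  what the usual `surv_cutpoint`/`maxstat` implementations maximize and
  lets the whole scan be vectorized. Ties break toward the smaller
  cutpoint. **Caveat:** the downstream log-rank p-value on the selected
  split is not corrected for the selection, so per-marker screening
  p-values are optimistic (anti-conservative); they are a ranking device,
  not calibrated tests. Corrected maxstat p-values are a non-goal.
* `cox_fit()` — Cox proportional hazards by Newton–Raphson on the Efron
  partial likelihood from β = 0, with step-halving so the log partial
  likelihood never decreases; SEs from the inverse observed information.
  Efron's tie correction is used because it is strictly more accurate than
  Breslow's and coincides with it when times are untied.
* `td_roc()` — cumulative-case / dynamic-control ROC at a horizon: cases
  are events by the horizon, controls are subjects still under observation
  beyond it, subjects censored before the horizon are excluded. The AUC is
  the trapezoid area and equals the Mann–Whitney statistic of case vs
  control scores. IPCW re-weighting is an extension hook; with moderate
  censoring at the median-time horizon the simple estimator is adequate for
  model comparison. The default horizon is the median observed time.

### Risk signature

All candidate lncRNAs enter one multivariate Cox model; signature members
are those with Wald p strictly below 0.05, and each patient's risk score is
`Σ expression_i · β_i` over members (log2-scale expression, uncentered —
the score is only ever compared to a cutpoint on the same scale). Patients
split into High/Low risk at the maximally selected cutpoint of the score by
default. A `split = "median"` alternative exists because an exact
half-half split (which published cohorts sometimes report) is a property of
the median, not of a maxstat scan; the default remains the scan.

### Hallmark propagation

`build_chart()` layers network lncRNA–mRNA edges, a gene→GO table and a
GO→hallmark table; RNAs with no route to a hallmark are dropped. The
association strength between a lncRNA and a hallmark is the number of
distinct (mRNA, GO term) pairs on connecting routes — so one mRNA reaching
a hallmark through three GO terms counts 3 — and `strong` means strictly
more than 2 paths. Counting (mRNA, GO) pairs rather than mRNAs alone is a
deliberate reading of "degree from the lncRNA": it matches how such
narratives count multiplicity, and it is monotone under removing neighbors.
GO-graph ancestor propagation is not performed; annotations are taken as
flat direct assignments, as delivered by the usual annotation services.

## The synthetic-data generator

`synth_config()` defines the study conditions; the generator is a pure
function of config + seed.

* **Expression** is an additive Gaussian latent-factor model on the log2
  scale: members of module *m* share a per-sample factor so each
  within-module pair has correlation ρ (default 0.9, which puts sample
  correlations at n ≈ 314 comfortably above the 0.85 edge gate while
  between-module pairs stay far below it). Gaussian log2-scale data — not
  negative-binomial counts — is the right target because every downstream
  statistic operates on log2 values. Planted DE genes get a tumor−normal
  mean shift of ±3 log2 units (sign alternating by module), ~5 standard
  errors beyond the |logFC| > 2 gate at the default cohort size.
* **Survival** is exponential proportional hazards for tumor samples:
  hazard `h0 · exp(Σ β_g · centered expression)`, with h0 = 1/1000 per day
  (median OS around two years, typical of an advanced-cancer cohort) and
  independent exponential censoring whose rate is solved numerically to hit
  the target censored fraction (default 0.55, consistent with risk-group
  mortalities around 60%/28%). The exponential baseline gives closed-form
  checks (null event times have mean 1/h0); a Weibull baseline is an
  extension hook.
* **Defaults** mirror the motivating study design: 283 tumor + 31 normal
  samples; 424 mRNA + 42 lncRNA candidates; four modules of sizes
  40/30/22/16 containing 88 mRNAs and 20 lncRNAs (8/6/4/2); two prognostic
  lncRNAs with β = ln 2, one in the largest module and one in the smallest.
  Unequal module sizes are deliberate: they give the network several
  distinct hub degrees so the degree-distribution stage is non-degenerate.
* **Annotation** draws 2 GO terms per mRNA from a 30-term vocabulary and
  maps every GO term to 1–2 of the ten canonical cancer hallmarks.

What the generator does **not** emulate — and hence what passing recovery
tests do not establish about real data: RSEM/RPKM quantification noise,
library-size and gene-length biases, batch effects, heavy-tailed or
count-discrete expression, non-proportional hazards, informative censoring,
and a scale-free degree distribution (four near-clique modules produce a
few large degrees, not a power-law tail; the power-law fit is therefore
validated on exactly constructed k^(−2) profiles instead).

## Numerical choices and degenerate inputs

* Newton–Raphson convergence: gradient max-norm or relative log-likelihood
  change below 1e-9, at most 50 iterations; non-convergence is a flagged
  warning with partial results, a singular information matrix
  (collinearity) is an error.
* Strictness is uniform: every published-style threshold (0.05, 0.85, 2)
  is applied with strict inequality, and the tests pin this at the
  boundary.
* Constant genes: an error for a single `pearson_edge()` call, a warned
  drop inside `build_network()`, p = 1 + flag in DE.
* The pipeline treats "no signature member reaches p < 0.05" as a reported
  outcome (empty signature, run continues), while direct calls to
  `build_signature()` raise an informative error — a screening run should
  say "nothing significant", a modelling call should fail loudly.
* Determinism: every generator takes an explicit seed and restores the
  caller's RNG state; pipeline reruns with one seed produce byte-identical
  TSVs whose header line carries a config fingerprint.

## Problem sizes used by the tests

Oracle comparisons run at deliberately small sizes where exhaustive
enumeration is exact (graphs ≤ 8 nodes, cutpoint scans ≤ 30 subjects,
Cox grid search at n = 8); recovery experiments run at the study scale
(314 samples) with reduced gene counts (30–50 genes, 20 seeds), and the
end-to-end pipeline runs at the full candidate scale (466 RNAs × 314
samples), which completes in a few seconds. Null-calibration experiments
use 500 Cox replicates at n = 200 and 10,000 log-rank permutations at
n = 60.

## Known limitations

* The Welch-t DE engine is a location test on log2 values, not a count
  model; with strongly skewed raw abundances its p-values are approximate.
* Screening p-values after cutpoint selection are anti-conservative (see
  above).
* Membership selection by unadjusted multivariate Wald p < 0.05 has a
  ~5% false-inclusion rate per non-prognostic candidate, so with ~20
  candidates the expected number of spurious signature members is ~1; on
  synthetic data the planted prognostic lncRNAs are recovered, but the
  member set is often a strict superset of the truth. This is a property
  of the selection rule itself, faithfully implemented.
* Highly collinear lncRNAs (within-module ρ = 0.9) inflate multivariate
  Cox standard errors, reducing power to flag each individual prognostic
  lncRNA even when the joint signal is strong.
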