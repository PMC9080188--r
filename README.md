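# lncnetsig

Long non-coding RNAs (lncRNAs) are mostly un-annotated, yet many act as key
regulators in cancer. A standard way to find candidate regulatory lncRNAs
in a tumor cohort — and to attach biology and prognosis to them — is an
inference chain that `lncnetsig` implements end to end, for bulk
tumor/normal expression studies (the package ships a synthetic-data
generator emulating a TCGA-style stomach-adenocarcinoma design: 283 tumor +
31 normal samples, mRNA + lncRNA profiles, overall survival in days):

1. **Differential expression.** On log2-transformed abundances, per-gene
   logFC = mean(tumor) − mean(normal) with a Welch t-test and
   Benjamini–Hochberg FDR; candidates must pass `FDR < 0.05` and
   `|logFC| > 2`.
2. **Co-expression network.** Edges between candidate RNA pairs with
   Pearson `R > 0.85` and `p < 0.05` (p from
   `t = R√(n−2)/√(1−R²)`); zero-degree nodes pruned; modules = connected
   components; hubs ranked by degree and betweenness centrality, degree
   distribution summarized by a log–log power-law fit.
3. **Survival screening.** Each network lncRNA's expression is split at the
   maximally selected cutpoint (standardized log-rank statistic maximized
   over splits with ≥ 10% of patients per side) and tested with
   Kaplan–Meier / log-rank at `p < 0.05`.
4. **Risk signature.** All network lncRNAs enter one multivariate Cox
   proportional-hazards model (Efron ties, Newton–Raphson); members are
   those with Wald `p < 0.05`, and each patient's risk score is

   `risk score = Σᵢ expᵢ · βᵢ`

   over the members (expᵢ = log2 expression, βᵢ = Cox coefficient).
   High/Low-risk groups from a cutpoint on the score, compared by log-rank,
   mortality rates and a time-dependent ROC/AUC at the median follow-up.
5. **Hallmark association.** lncRNA → mRNA (network edge) → GO term
   (annotation) → cancer hallmark (mapping table); the association strength
   is the number of distinct (mRNA, GO) paths and is called *strong* when
   it exceeds 2.

All survival statistics (Kaplan–Meier, log-rank, maximally selected
cutpoint, Cox, time-dependent ROC) are implemented in the package and
verified in the test suite against brute-force oracles and the `survival`
package.

## Worked example

The default configuration generates a synthetic cohort shaped like the
motivating study (424 mRNA + 42 lncRNA candidates, 314 samples, four
correlated modules holding 88 mRNAs + 20 lncRNAs, two prognostic lncRNAs
with β = ln 2):

```r
library(lncnetsig)
cfg <- pipeline_config(synth = synth_config(seed = 1), seed = 1)
p <- run_pipeline(cfg)
print(p)
#> lncRNA-mRNA network & signature pipeline
#>   candidates: 466 of 466 genes pass the DE gate
#> corr_network: 108 nodes (20 lncRNA, 88 mRNA), 1566 edges, 4 module(s)
#>   gates: r > 0.85, p < 0.05 over 314 all sample(s)
#>   screening: 15 / 20 lncRNAs associated with OS (p < 0.05)
#>   signature: LNC0019
#>   mortality High vs Low risk: 56.54% vs 25.00%; AUC = 0.6938; log-rank p = 2.798e-08
#>   hallmark associations: 188 (176 strong)
```

Reading this: all 466 planted DE genes pass the gate; the network keeps
exactly the 108 correlated-module genes in 4 modules; 15 of the 20 network
lncRNAs show a significant KM split (cutpoint screening is intentionally
permissive — see the methods vignette); the multivariate Cox model flags
the planted prognostic lncRNA `LNC0019` (β = 1.09, HR = 2.98,
p = 4.7e-06), and the resulting risk score separates mortality 56.5% vs
25.0% with AUC 0.69 at median follow-up. The per-lncRNA screening report:

```r
head(p$screening, 3)
#>   gene_id cutpoint n_low n_high chi_square      p_value significant
#> 1 LNC0003 6.468970   140    143   37.28150 1.022499e-09        TRUE
#> 2 LNC0008 9.674609   141    142   36.15028 1.826726e-09        TRUE
#> 3 LNC0007 6.178720   181    102   35.07524 3.172085e-09        TRUE
```

Setting `outdir` in `pipeline_config()` writes every stage table as TSV
(DE table, edge/node lists, topology, screening report, Cox fit, signature
scores, ROC points, hallmark associations), byte-identical across reruns
with the same seed. `inst/scripts/run_pipeline.R` is a command-line
wrapper over the same function, and each stage is equally usable on your
own data frames (`read_expression()`, `merge_profiles()`, `preprocess()`,
`differential_expression()`, `build_network()`, `screen_survival()`,
`build_signature()`, `build_chart()`, ...).

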