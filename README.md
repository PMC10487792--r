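# sigforge

Discovering a prognostic gene signature from multiple tumor/normal
expression cohorts — and using it to define molecular subtypes with distinct
survival — is a common design in cancer transcriptomics: differentially
expressed genes (DEGs) that replicate across cohorts are grouped by
function, the most representative and most perturbed genes are kept, and
the resulting signature clusters an independent cohort into subtypes that
are then compared clinically. `sigforge` implements that pipeline end to
end for R users working with bulk expression matrices, plus a synthetic
study generator with planted ground truth so the whole pipeline can be
exercised and validated offline.

## The scoring model

Candidate genes are the up-regulated DEGs shared by every cohort
(|fold change| ≥ 1.5 and Welch-test *p* < 0.05 per cohort, fold change
taken as 2^(Δ of log2 means)). Three scores drive selection:

- **Cluster score (CS)** for a gene pair *i, j*:

      CS_ij = (RSS_BP(i,j) + RSS_CC(i,j)) / 2  +  (1/N) Σ_n PCC_ij(n)

  where RSS is the relative specificity similarity of the genes'
  Gene Ontology annotations (biological process and cellular component,
  best-match averaged over term pairs; for terms,
  RSS(a,b) = max over common ancestors c of depth(c) / (depth(c) + d(a,c) + d(b,c)))
  and PCC is the Pearson co-expression over the tumor samples of each of
  the N cohorts. CS ranges over [−1, 2]. Genes are grouped by
  average-linkage clustering of CS row profiles (Spearman ρ > 0.6), and
  groups are kept only when at least one GOBP term is hypergeometrically
  enriched at *p* < 0.05 with ≥ 3 group members.

- **Representative score (RS)**: RS_i = Σ_{j≠i in group} CS_ij / (2M) —
  how central a gene is to its functional group of size M.

- **Perturbation score (PS)**: per cohort the sum of a gene's rescaled
  |log2 fold change|, significance (1 − p), and counts of co-expressed
  interaction partners (NIG: PPI partners with |r| ≥ 0.5; NCG: for genes
  with no PPI records, other genes with |r| ≥ 0.7); per-cohort sums are
  rank-transformed, averaged, and min–max normalised to [0, 1].

Each group keeps its top genes by the geometric mean √(RS·PS), with a
per-group quota SC = (G − min(G))/min(G) + min(G) (G = group size, min(G)
= smallest eligible group). The signature union then drives sample
subtyping (1 − Spearman dissimilarity over z-scored signature genes,
average linkage, cut at ρ ≥ 0.7) and survival comparison (Kaplan–Meier,
log-rank, univariable Cox with Breslow ties; 5-year horizon).

## Worked example

```r
library(sigforge)

study  <- simulate_study(sim_config(seed = 1))
result <- run_pipeline(study$cohorts, study$validation, study$go,
                       study$ppi, study$clinical, study$hallmarks)
result
#> <sig_pipeline>
#>   candidates (up in all cohorts): 97
#>   gene groups: 11 | eligible: 9
#>   signature genes: 74
#>   subtypes: 3

tidy(result$survival)
#> # A tibble: 3 × 7
#>   cluster_a cluster_b logrank_chi2 logrank_p    hr hr_low hr_high
#>       <int>     <int>        <dbl>     <dbl> <dbl>  <dbl>   <dbl>
#> 1         1         2     0.000416  0.984     1.00  0.753    1.34
#> 2         1         3    11.1       0.000878  1.81  1.27     2.58
#> 3         2         3    11.3       0.000780  1.85  1.29     2.67

result$annotation$frequencies
#> # A tibble: 3 × 5
#>   cluster     n hpv_positive smoking_current tp53_mutant
#>     <int> <int>        <dbl>           <dbl>       <dbl>
#> 1       1   138       0.0652           0.435       0.732
#> 2       2   121       0.0165           0.124       0.694
#> 3       3    86       0.674            0.198       0.593
```

Of 2,000 simulated genes, 97 shared up-regulated candidates survive the
three-cohort intersection (100 were planted); they fall into 11 CS-based
groups of which 9 pass the GOBP gate, yielding a 74-gene signature. The
345-tumor validation cohort splits into three subtypes that recover the
planted assignment exactly: the small HPV-enriched cluster (67% positive)
has the best survival (hazard ratios ≈ 1.8 against it, log-rank
*p* < 0.001), while the smoking-enriched and remaining HPV-negative
clusters are indistinguishable from each other (*p* = 0.98) — the planted
hazard ratios were 1.39/1.36/1. `plot_km(result$survival)`,
`plot_cs_heatmap()` and `plot_signature_scores()` draw the corresponding
figures; `hnsc88_signature()` ships the published 88-gene head-and-neck
signature with its 11 functional groups as a reference fixture.

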