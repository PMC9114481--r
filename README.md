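# lncmeth

Promoter methylation analysis of long noncoding RNAs (lncRNAs) in tumor
cohorts profiled on Illumina-style DNA methylation arrays.

Most of what we know about tumor DNA methylation concerns protein-coding
genes, yet lncRNA promoters are methylated too, and their methylation
carries information about tumor subtype, the immune microenvironment, and
patient outcome. `lncmeth` packages that analysis as a tested, reusable R
pipeline for anyone working with beta-value matrices (e.g. 450K/EPIC
arrays): epigenomics researchers studying lncRNA regulation, and
computational groups doing methylation-based subtyping of tumor cohorts.

## What it computes

Given a probe manifest, a samples × probes beta matrix (β ∈ [0, 1]), a gene
annotation, a cell-type reference signature, and clinical follow-up, the
pipeline:

1. **Filters probes** (sex chromosomes, SNP overlap, non-unique mapping,
   absent from EPIC) and maps the rest to **4-kb promoters** centered on
   strand-aware TSSs.
2. **Categorizes each lncRNA** by promoter methylation:
   *hyper* if mean promoter β > 0.7 in more than 80% of samples,
   *hypo* if β < 0.3 in more than 80%, *inter* otherwise — and compares
   sequence features (GC content, CpG observed/expected ratio
   O/E = obs(CG)/(GC/2)², conservation, exon counts) across categories
   with KS and rank-sum tests.
3. **Discovers methylation subtypes** by resampled consensus clustering of
   the top 5% most-variable promoter probes (50 iterations, 0.8 resampling,
   k-means under Pearson-correlation geometry), choosing k by the
   proportion of ambiguous clustering (PAC).
4. **Deconvolves immune/stromal cell fractions** from a 10-cell-type CpG
   signature (CD14, CD19, CD4_Eff, CD56, CD8, Endothelial, Eos, Fib, Neu,
   Treg) by non-negative least squares (or CIBERSORT-style nu-SVR), with a
   100-permutation empirical p-value per sample.
5. **Identifies infiltration-related lncRNAs** per subtype: Spearman
   correlation between promoter methylation and each cell fraction, called
   at |rho| > 0.3 and BH-adjusted p < 0.05; tests category enrichment among
   the calls; links lncRNAs to immune-pathway protein-coding genes within
   10 kb; runs one-vs-rest differential methylation (|Δβ| > 0.2, p < 0.05).
6. **Evaluates prognosis**: dichotomizes samples at the maximally selected
   log-rank cutpoint of a lncRNA's methylation, compares survival by
   log-rank, and quantifies the added prognostic value of methylation
   subtypes through nested Cox models (age+sex ⊂ +WHO category ⊂ +subtype)
   with likelihood-ratio chi-square tests.

A first-class synthetic-data module (`synthetic_config()`,
`simulate_beta()`, `simulate_survival()`) generates cohorts with fully
known planted truth — clusters, methylation categories, cell-type mixtures,
methylation–infiltration correlations, cluster-dependent hazards — so every
stage is testable without any download.

## Worked example

```r
library(lncmeth)

cfg <- synthetic_config(n_samples = 150, n_clusters = 2, n_lncrna = 200,
                        hazard_ratio = 3, seed = 11)
sim <- simulate_beta(cfg)

retained <- filter_probes(sim$annotation$probes)
prom <- promoter_of(sim$annotation$genes[
  sim$annotation$genes$biotype == "lncRNA", ])
pm <- summarize_promoter(sim$beta, map_probes_to_promoters(retained, prom))
table(categorize(pm)$label)
#> hyper  hypo inter
#>    58    76    59

top <- select_variable_probes(sim$beta[, retained$probe_id], 0.05)
cc <- consensus_cluster(sim$beta[, top], k_range = 2:5, seed = 12)
cc
#> Consensus clustering over k = 2..5
#> PAC: k=2 0.000, k=3 0.368, k=4 0.435, k=5 0.415
#> chosen k: 2

fr <- deconvolve(sim$beta, sim$signature)
round(head(fr[, c("CD8", "Treg", "Fib", "rmse", "corr")], 3), 3)
#>         CD8  Treg   Fib  rmse  corr
#> S0001 0.072 0.175 0.103 0.028 0.846
#> S0002 0.175 0.082 0.138 0.026 0.861
#> S0003 0.116 0.052 0.069 0.026 0.770

surv <- simulate_survival(sim$truth, cfg)
surv$lncrna_cluster <- cc$assignment[surv$sample_id]
nested_cox_lr(surv)
#>                                  tier    loglik n_coef  delta_lr df            p
#> 1                             age+sex -448.2627      2        NA NA           NA
#> 2                age+sex+who_category -446.1794      4  4.166465  2 1.245270e-01
#> 3 age+sex+who_category+lncrna_cluster -431.2503      5 29.858329  1 4.647959e-08
```

The categorization recovers the planted 30% hyper / 40% hypo proportions;
PAC drops to zero only at the planted k = 2, whose assignment matches the
planted clusters exactly (adjusted Rand index 1); and the methylation
subtype adds a large likelihood-ratio increment (ΔLR ≈ 29.9 on 1 df,
p ≈ 5e-8) beyond the clinical covariates, reflecting the planted 3-fold
hazard ratio between subtypes.

`run_pipeline(pipeline_config(outdir = "out", seed = 1))` executes all six
stages end to end, writing every intermediate table as TSV plus a manifest
of MD5 hashes; `inst/scripts/lncmeth.R` wraps this as a shell entry point.

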