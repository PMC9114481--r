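---
title: "Methods: lncRNA promoter methylation analysis with lncmeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lncRNA promoter methylation analysis with lncmeth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncmeth)
```

`lncmeth` analyses promoter-level DNA methylation of long noncoding RNAs
(lncRNAs) in tumor cohorts. This vignette explains the models and
procedures each stage implements, the parameters that matter and their
defaults, what the synthetic-data generator does and does not emulate, and
the numerical choices made where the design was genuinely open.

## Promoter methylation and the three-way categorization

A gene's promoter is the 4-kb window centered on its strand-aware TSS
(`promoter_of()`, `flank = 2000` bases per side; intervals are 0-based
half-open, clipped at chromosome edges). Array probes surviving the
standard cross-study filters — sex chromosomes, SNP overlap, non-unique
mapping, absence from the EPIC array, all carried as manifest flags rather
than recomputed from external databases — are assigned to every promoter
containing their position; a probe inside two overlapping promoters counts
for both, since lncRNA and protein-coding promoters are mapped
independently. Promoter methylation of gene *g* in sample *s* is the mean
beta of its non-missing mapped probes.

The cohort-level categorization rule is threshold-based: a lncRNA is
**hyper**-methylated when promoter beta exceeds 0.7 in more than 80% of
samples, **hypo**-methylated when below 0.3 in more than 80%, and
**inter**-methylated otherwise. All three cut values (`hyper = 0.7`,
`hypo = 0.3`, `sample_fraction = 0.8`) are arguments of `categorize()`.
Two reading choices deserve note: "more than" is taken strictly (a gene at
exactly 80% is inter — the edge case is tested), and fractions are computed
over *non-missing* samples per gene, so probe dropout does not bias a gene
toward inter. Per-cancer-type categorization is the same rule applied to
sample subsets (`groups =`).

Sequence features compared across categories follow the classic CpG-island
conventions: GC content excludes N bases from numerator and denominator;
the normalized CpG ratio is obs(CG)/(L − 1) divided by (GC/2)², with the
L − 1 denominator counting overlapping dinucleotide windows. Distributional
features (GC, CpG O/E) are compared by Kolmogorov–Smirnov, count-like
features (conservation, CpG and exon counts) by Wilcoxon rank-sum
(`compare_feature_by_category()`). A closed form worth recording: for the
sequence "CG" + "AT"×k the ratio is 4(k+1)²/(2k+1), *increasing* in k —
AT-dilution shrinks the expected CpG faster than the observed, so a high
O/E alone does not imply CpG density.

## Consensus subtyping

Subtypes are discovered on the top 5% most variable lncRNA-promoter probes
(SD over non-missing samples; boundary ties broken by probe id so the
selection is deterministic; the realized SD cutoff is attached to the
result). `consensus_cluster()` then runs the resampling scheme: in each of
`iterations = 50` rounds, `resample = 0.8` of the samples are drawn without
replacement and clustered; the consensus entry for a sample pair is the
number of rounds they co-clustered divided by the number of rounds they
were co-sampled. The same subsample draws are reused across candidate k so
PAC curves are comparable.

Open design points, and the choices made:

* **Base clusterer.** k-means in the Pearson-correlation geometry: each
  sample's feature vector is z-scored, under which Euclidean k-means is
  equivalent to clustering on 1 − r. k-means uses 5 random restarts per
  fit: on well-separated planted blobs a single-start k-means falls into a
  high-inertia local optimum in roughly half of runs, and that solver
  artifact would masquerade as clustering ambiguity in the consensus
  matrix.
* **Final assignment** at each k cuts an average-linkage dendrogram of
  1 − consensus, the established consensus-clustering convention.
* **Model selection.** PAC, the fraction of off-diagonal consensus entries
  strictly inside `pac_window = c(0.1, 0.9)`, is minimized over `k_range`
  (default 2:10 at desk scale; the procedure accepts any range). Ties at
  the minimum go to the **largest** tied k: when the planted structure is
  hierarchical, the coarse merge of clean clusters is itself perfectly
  stable (PAC = 0 at k = 2 *and* at the true k), and the finest
  unambiguous partition is the one sought.

## Cell-type deconvolution

`deconvolve()` estimates the mixing fractions of a bulk beta profile over a
probes × cell-types reference signature (the 10-population immune/stromal
panel by default). The default solver is non-negative least squares on raw
betas — transparent, fast, and exact on noiseless mixtures. The
`nu_svr` option fits a linear nu-support-vector regression (nu ∈
{0.25, 0.5, 0.75}, best kept by reconstruction RMSE, negative coefficients
clipped), with profile and signature each standardized **globally** — a
single mean and SD for the whole signature matrix. Per-column
standardization would rescale each cell type's coefficient by its column
SD, a systematic bias; with global scaling the two solvers agree to ~1e-4
on noiseless mixtures. Either way coefficients are clipped at zero first
and then renormalized to sum to 1 (the fixed clip-then-normalize order
makes fractions well-defined); no quantile normalization is applied
anywhere. Fit quality is reported as reconstruction RMSE and Pearson r,
and `permutation_p()` gives an empirical p-value by redistributing the
profile's values across probes (`n_perm = 100`), with the add-one
estimator, so the smallest attainable p is 1/101 ≈ 0.0099.

Per-subtype contrasts of the estimated fractions use one-way ANOVA per
cell type (`fractions_by_cluster()`); mean-methylation signature scores
over named CpG sets (checkpoints, CYT, HLA, IFN, TILs, response panels)
are plain set means (`signature_score()`).

## Infiltration-related lncRNAs

Within each subtype of at least `min_cluster = 10` samples,
`spearman_assoc()` correlates every lncRNA's promoter methylation with
every cell-type fraction: Spearman rho with average ranks, p from the t
approximation. Benjamini–Hochberg adjustment is applied across lncRNAs
*within each (cluster, cell type) stratum* — the adjustment scope matches
the per-cluster, per-cell-type reporting of the call lists; Bonferroni is
available. A call requires both |rho| > 0.3 and adjusted p < 0.05; the
magnitude filter means the procedure is more conservative than BH alone,
and on fully null synthetic cohorts the false-call rate is two orders of
magnitude below 0.05 (measured by the acceptance script). Category
enrichment among called lncRNAs is Fisher's exact test on the 2×2
membership table.

Pathway involvement is assigned by genomic proximity: a lncRNA inherits
the immune-pathway annotations of every protein-coding gene whose interval
hull lies within `window = 10000` bases (gap 0 when intervals overlap;
boundary inclusive, so a gap of exactly 10 kb links). Distance between
hulls, not TSSs, is the default because "within 10 kb" reads most
naturally as interval proximity; a TSS-to-TSS mode is available.
One-vs-rest differential methylation uses the Welch two-sample t-test
(cluster sizes and variances differ grossly in this design), computed
vectorized from summary statistics and verified against `t.test()`; calls
require |Δβ| > 0.2 *and raw* p < 0.05 — the raw-p convention is
deliberate and asymmetric with the adjusted-p association calls.

## Survival

`optimal_cutpoint()` implements the maximally selected log-rank statistic:
log-rank scores a_i = δ_i − Λ̂(t_i) from the tie-aware Nelson–Aalen
cumulative hazard; for every threshold between consecutive distinct marker
values leaving at least `min_prop = 0.1` of samples on each side, the
standardized score sum of the induced low group under the permutation
hypothesis; the maximizing threshold wins. Complementary splits produce
mathematically identical statistics that differ only in floating point, so
ties are resolved at 1e-12 tolerance toward the more balanced split, then
the smaller cutpoint — and the whole scan is verified against an
independent brute-force oracle. The log-rank p reported after cutpoint
selection is the naive one, as Kaplan–Meier panels conventionally show; it
does not account for cutpoint optimism.

`nested_cox_lr()` fits Cox proportional-hazards models (Efron tie
handling, via the survival package) for the tier sequence
age+sex ⊂ +WHO category ⊂ +methylation subtype, and tests each increment
by ΔLR = 2Δloglik against chi-square with df equal to the number of added
coefficients. Adding a collinear covariate contributes zero coefficients
and the increment p is NA rather than a spurious test.

## The synthetic cohort and what passing tests mean

`simulate_beta()` draws every beta value from Beta(μφ, (1−μ)φ), the
natural bounded noise law for array betas: mean μ, variance
μ(1−μ)/(φ+1), so `beta_precision` φ is an inverse-noise knob
(φ = 200 ≈ SD 0.025 at μ = 0.85; φ = Inf switches noise off). Planted
structure enters through μ:

* categories — μ = 0.85 / 0.15 / 0.5 for hyper/hypo/inter (noiseless
  promoter means reproduce the categorization rule exactly, by
  construction 0.85 > 0.7 and 0.15 < 0.3);
* subtypes — inter lncRNAs not used for association planting carry a
  cluster-specific shift of ±`cluster_shift` with a non-constant sign
  pattern across clusters, chosen so no balanced cluster design can push a
  planted inter gene over the 80% categorization margin;
* infiltration coupling — for `n_assoc` lncRNAs, μ is a Gaussian-copula
  monotone function of one cell-type fraction with latent correlation
  2·sin(π·rho/6), the exact inverse of the Spearman-to-Pearson relation
  for bivariate normals, so the planted Spearman rho is calibrated rather
  than approximate (rank-preserving coupling, because the association
  statistic only sees ranks);
* mixtures — symmetric Dirichlet rows (concentration 2), multiplied
  through the block signature for signature probes;
* survival — exponential event times with the last cluster's hazard
  multiplied by `hazard_ratio`, censoring uniform on (0, τ) with τ solved
  numerically so the expected censored fraction equals `censor_rate`, and
  age, sex, WHO category independent of outcome so the nested-Cox null is
  calibrated.

Defaults mirror the category proportions typical of lncRNA promoters
(30% hyper, 40% hypo) and a two-subtype cohort of 100 samples on one
synthetic chromosome; protein-coding genes are placed half within 10 kb of
a lncRNA and half beyond, with the linkage truth recorded. The generator
deliberately does **not** emulate raw IDAT intensities, background or
dye-bias artifacts, batch effects, probe cross-hybridization chemistry, or
correlated noise between neighboring probes. Passing tests therefore
demonstrate that the statistical machinery recovers planted truth under
bounded beta-distributed noise — they do not certify performance on real
arrays with unmodeled technical structure, and φ is a calibration knob,
not an estimate of any real array's noise.

Problem sizes used by the test suite and acceptance script — 200 samples ×
2,000 lncRNAs for categorization, 200 samples with 4 planted subtypes for
clustering, 100 Dirichlet mixtures for deconvolution, 50 cohorts of 100
samples for association sensitivity plus 500 null cohorts for the
false-call rate, 200 random instances (n ≤ 30) for the cutpoint oracle,
and 1,000 + 200 replicates for Cox LR calibration and power — are the
package's chosen desk-scale study conditions; the same code runs unchanged
at cohort scale.

## Known limitations

* No normalization, batch correction, or cross-array harmonization: the
  beta matrix is assumed preprocessed.
* Consensus clustering cost grows with iterations × |k_range| × n; the
  PAC tie rule assumes the resampling is informative (degenerate inputs
  with all-zero variance are warned about, not rescued).
* The deconvolution reports relative fractions (sum 1), never absolute
  abundances, and does not derive new signatures from purified references.
* Cutpoint p-values are not corrected for the maximal selection unless the
  permutation option is used; competing risks and time-varying covariates
  are out of scope.
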