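#' Configuration for the synthetic methylation cohort
#'
#' Bundles every knob of the synthetic-data generator: cohort size, planted
#' cluster structure, planted promoter methylation categories, reference
#' cell-type mixtures, planted methylation-infiltration correlations, and
#' cluster-dependent survival. The defaults describe a small cohort with the
#' category proportions typical of lncRNA promoters on methylation arrays
#' (roughly 30% hyper- and 40% hypo-methylated).
#'
#' @param n_samples number of tumor samples.
#' @param n_clusters number of planted methylation subtypes (balanced).
#' @param n_lncrna number of lncRNA genes.
#' @param n_pcg number of protein-coding genes.
#' @param probes_per_promoter mean number of CpG probes per 4-kb promoter.
#' @param n_cell_types number of reference cell types (10 gives the standard
#'   immune/stromal panel names).
#' @param probes_per_cell_type discriminating probes per cell type in the
#'   reference signature.
#' @param beta_precision concentration `phi` of the Beta noise law for array
#'   beta values; a draw has mean `mu` and variance `mu(1-mu)/(phi+1)`.
#'   `Inf` switches noise off.
#' @param cluster_shift planted between-cluster promoter methylation
#'   difference, in beta units, applied to cluster-informative probes.
#' @param frac_hyper,frac_hypo fractions of lncRNAs planted hyper- and
#'   hypo-methylated; the remainder is inter-methylated.
#' @param n_assoc number of lncRNAs whose promoter methylation is coupled to
#'   one cell-type fraction (half positively, half negatively).
#' @param assoc_rho target Spearman correlation magnitude of the planted
#'   couplings, in (-1, 1).
#' @param hazard_ratio hazard ratio of the last planted cluster relative to
#'   the others (1 = no survival effect).
#' @param censor_rate target fraction of censored samples.
#' @param flag_fraction fraction of probes carrying each exclusion flag
#'   (chromosome X/Y, SNP overlap, non-unique mapping, absent from EPIC).
#' @param dirichlet_alpha concentration of the Dirichlet law for per-sample
#'   cell-type mixtures.
#' @param seed integer seed; all generator outputs are deterministic in it.
#'
#' @return An object of class `synthetic_config` (a validated list).
#' @seealso [generate_annotation()], [generate_signature()],
#'   [simulate_beta()], [simulate_survival()]
#' @export
synthetic_config <- function(n_samples = 100, n_clusters = 2, n_lncrna = 200,
                             n_pcg = 100, probes_per_promoter = 3,
                             n_cell_types = 10, probes_per_cell_type = 50,
                             beta_precision = 200, cluster_shift = 0.3,
                             frac_hyper = 0.3, frac_hypo = 0.4,
                             n_assoc = 20, assoc_rho = 0.5,
                             hazard_ratio = 2, censor_rate = 0.3,
                             flag_fraction = 0.05, dirichlet_alpha = 2,
                             seed = 1) {
  config <- list(n_samples = as.integer(n_samples),
                 n_clusters = as.integer(n_clusters),
                 n_lncrna = as.integer(n_lncrna),
                 n_pcg = as.integer(n_pcg),
                 probes_per_promoter = probes_per_promoter,
                 n_cell_types = as.integer(n_cell_types),
                 probes_per_cell_type = as.integer(probes_per_cell_type),
                 beta_precision = beta_precision,
                 cluster_shift = cluster_shift,
                 frac_hyper = frac_hyper, frac_hypo = frac_hypo,
                 n_assoc = as.integer(n_assoc), assoc_rho = assoc_rho,
                 hazard_ratio = hazard_ratio, censor_rate = censor_rate,
                 flag_fraction = flag_fraction,
                 dirichlet_alpha = dirichlet_alpha,
                 seed = as.integer(seed))
  class(config) <- "synthetic_config"
  validate_synthetic_config(config)
  config
}

validate_synthetic_config <- function(config) {
  with(config, {
    if (any(c(n_samples, n_clusters, n_lncrna, n_pcg, n_cell_types) < 1))
      stop("all counts must be >= 1")
    if (n_clusters > n_samples)
      stop("n_clusters must not exceed n_samples")
    if (frac_hyper < 0 || frac_hypo < 0 || frac_hyper + frac_hypo > 1)
      stop("frac_hyper + frac_hypo must lie in [0, 1]")
    if (!is.infinite(beta_precision) && beta_precision <= 0)
      stop("beta_precision must be positive")
    if (cluster_shift < 0 || cluster_shift > 0.5)
      stop("cluster_shift must lie in [0, 0.5]")
    if (abs(assoc_rho) >= 1)
      stop("assoc_rho must lie in (-1, 1)")
    if (hazard_ratio <= 0)
      stop("hazard_ratio must be positive")
    if (censor_rate < 0 || censor_rate >= 1)
      stop("censor_rate must lie in [0, 1)")
    if (flag_fraction < 0 || flag_fraction >= 1)
      stop("flag_fraction must lie in [0, 1)")
    if (probes_per_promoter < 1)
      stop("probes_per_promoter must be >= 1")
  })
  invisible(config)
}

#' Standard immune/stromal cell-type panel names
#'
#' The 10 reference populations of the methylation deconvolution signature:
#' monocyte lineage (CD14), B cells (CD19), effector CD4 T cells (CD4_Eff),
#' NK cells (CD56), cytotoxic T cells (CD8), endothelial cells, eosinophils,
#' fibroblasts, neutrophils, and regulatory T cells.
#'
#' @param n number of cell types; the canonical names are used when `n <= 10`,
#'   generic `CT<i>` names beyond that.
#' @return character vector of length `n`.
#' @export
cell_type_names <- function(n = 10) {
  canonical <- c("CD14", "CD19", "CD4_Eff", "CD56", "CD8",
                 "Endothelial", "Eos", "Fib", "Neu", "Treg")
  if (n <= length(canonical)) canonical[seq_len(n)]
  else c(canonical, paste0("CT", seq_len(n - length(canonical))))
}
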