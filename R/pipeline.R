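#' Configuration of the end-to-end analysis pipeline
#'
#' Collects every stage parameter of [run_pipeline()] plus the
#' synthetic-cohort configuration used when the pipeline generates its own
#' inputs. All thresholds default to the analysis conventions: promoter
#' categorization at beta 0.7/0.3 in more than 80% of samples, top 5%
#' variable probes, consensus clustering with 50 iterations at resampling
#' rate 0.8, Spearman calls at |rho| > 0.3 and adjusted p < 0.05,
#' differential methylation at |delta beta| > 0.2 and p < 0.05, pathway
#' linkage within 10 kb, cutpoint groups of at least 10% of samples.
#'
#' @param outdir output directory (created if absent).
#' @param synth a [synthetic_config()] for the data-generation stage.
#' @param flank promoter flank in bases.
#' @param hyper,hypo,sample_fraction categorization rule parameters.
#' @param top_fraction fraction of most-variable probes kept for clustering.
#' @param k_range,iterations,resample consensus clustering parameters.
#' @param deconv_method `"nnls"` or `"nu_svr"`.
#' @param n_perm permutations for deconvolution significance.
#' @param rho_threshold,alpha association-call thresholds.
#' @param min_cluster minimum per-cluster sample count for associations.
#' @param window pathway-linkage distance in bases.
#' @param delta_threshold differential-methylation effect threshold.
#' @param min_prop minimum group fraction for the survival cutpoint.
#' @param seed global seed; per-stage seeds are derived from it.
#' @param resume skip stages whose outputs already exist.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir, synth = synthetic_config(),
                            flank = 2000, hyper = 0.7, hypo = 0.3,
                            sample_fraction = 0.8, top_fraction = 0.05,
                            k_range = 2:6, iterations = 50, resample = 0.8,
                            deconv_method = "nnls", n_perm = 100,
                            rho_threshold = 0.3, alpha = 0.05,
                            min_cluster = 10, window = 10000,
                            delta_threshold = 0.2, min_prop = 0.1,
                            seed = 1, resume = FALSE) {
  config <- as.list(environment())
  class(config) <- "pipeline_config"
  config
}

#' Validate a pipeline configuration
#'
#' @param config a [pipeline_config()].
#' @return character vector of violations (field name and admissible
#'   range); `character(0)` when the configuration is valid.
#' @export
validate_config <- function(config) {
  errors <- character(0)
  chk <- function(cond, msg) if (!cond) errors <<- c(errors, msg)
  chk(inherits(config$synth, "synthetic_config"),
      "synth: must be a synthetic_config")
  if (inherits(config$synth, "synthetic_config"))
    tryCatch(validate_synthetic_config(config$synth),
             error = function(e) chk(FALSE, paste0("synth: ", e$message)))
  chk(config$flank > 0, "flank: must be > 0")
  chk(config$hyper > 0 && config$hyper < 1, "hyper: must lie in (0, 1)")
  chk(config$hypo > 0 && config$hypo < 1, "hypo: must lie in (0, 1)")
  chk(config$hypo < config$hyper, "hypo: must be smaller than hyper")
  chk(config$sample_fraction > 0 && config$sample_fraction < 1,
      "sample_fraction: must lie in (0, 1)")
  chk(config$top_fraction > 0 && config$top_fraction <= 1,
      "top_fraction: must lie in (0, 1]")
  chk(all(config$k_range >= 2), "k_range: must be >= 2")
  chk(max(config$k_range) <= config$synth$n_samples,
      "k_range: k_max must not exceed n_samples")
  chk(config$iterations >= 1, "iterations: must be >= 1")
  chk(config$resample > 0 && config$resample <= 1,
      "resample: must lie in (0, 1]")
  chk(config$deconv_method %in% c("nnls", "nu_svr"),
      "deconv_method: must be nnls or nu_svr")
  chk(config$n_perm >= 10, "n_perm: must be >= 10")
  chk(config$rho_threshold >= 0 && config$rho_threshold < 1,
      "rho_threshold: must lie in [0, 1)")
  chk(config$alpha > 0 && config$alpha < 1, "alpha: must lie in (0, 1)")
  chk(config$window >= 0, "window: must be >= 0")
  chk(config$delta_threshold > 0 && config$delta_threshold < 1,
      "delta_threshold: must lie in (0, 1)")
  chk(config$min_prop > 0 && config$min_prop < 0.5,
      "min_prop: must lie in (0, 0.5)")
  chk(is.numeric(config$seed) && length(config$seed) == 1,
      "seed: must be a single integer")
  errors
}

pipeline_stage_files <- function(outdir) {
  list(
    synth = file.path(outdir, c("annotation.tsv", "manifest.tsv", "beta.tsv",
                                "signature.tsv", "survival.tsv",
                                "pathways.tsv", "truth_clusters.tsv",
                                "truth_categories.tsv", "truth_assoc.tsv",
                                "config_echo.tsv")),
    categorize = file.path(outdir, c("promoter_methylation.tsv",
                                     "categories.tsv")),
    cluster = file.path(outdir, c("cluster_assignments.tsv", "pac.tsv",
                                  "consensus.tsv", "sample_correlation.tsv")),
    deconvolve = file.path(outdir, c("cell_fractions.tsv",
                                     "fraction_anova.tsv")),
    immune_lncrna = file.path(outdir, c("associations.tsv",
                                        "category_enrichment.tsv",
                                        "pathway_links.tsv",
                                        "pathway_counts.tsv",
                                        "diff_methylation.tsv")),
    survival = file.path(outdir, c("cox_lr.tsv", "cutpoint.tsv", "km.tsv")))
}

#' Run the full analysis pipeline
#'
#' Executes the six stages in dependency order — synthetic-cohort
#' generation, promoter categorization, consensus subtyping, cell-type
#' deconvolution, immune-lncRNA association, survival analysis — with every
#' stage consuming its inputs from the files written by the previous ones,
#' so each stage is independently re-runnable. All stage seeds derive
#' deterministically from the global seed; identical configurations produce
#' identical output hashes. With `resume = TRUE`, stages whose output files
#' all exist are skipped.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, the run manifest: data frame with `stage`, `file`,
#'   `md5`.
#' @export
run_pipeline <- function(config) {
  errors <- validate_config(config)
  if (length(errors))
    stop("invalid configuration:\n  ", paste(errors, collapse = "\n  "))
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- pipeline_stage_files(outdir)
  stage_done <- function(stage) {
    isTRUE(config$resume) && all(file.exists(files[[stage]]))
  }

  ## stage 1: synthetic cohort -------------------------------------------
  if (!stage_done("synth")) {
    cohort <- simulate_beta(config$synth)
    surv <- simulate_survival(cohort$truth, config$synth)
    set.seed(derive_seed(config$synth$seed, "pathways"))
    pcg_ids <- cohort$annotation$genes$gene_id[
      cohort$annotation$genes$biotype == "protein_coding"]
    n_member <- stats::rbinom(length(pcg_ids), 3, 0.4)
    pathways <- do.call(rbind, lapply(seq_along(pcg_ids), function(i) {
      if (n_member[i] == 0) return(NULL)
      data.frame(gene_id = pcg_ids[i],
                 pathway = sample(sprintf("PW%02d", 1:17), n_member[i]),
                 stringsAsFactors = FALSE)
    }))
    if (is.null(pathways))
      pathways <- data.frame(gene_id = character(0), pathway = character(0))
    write_tsv(cohort$annotation$genes, files$synth[1])
    write_tsv(cohort$annotation$probes, files$synth[2])
    write_tsv(cohort$beta, files$synth[3], rownames = "id")
    write_tsv(cohort$signature, files$synth[4], rownames = "probe_id")
    write_tsv(surv, files$synth[5])
    write_tsv(pathways, files$synth[6])
    write_tsv(data.frame(sample_id = names(cohort$truth$cluster_of_sample),
                         cluster = unname(cohort$truth$cluster_of_sample)),
              files$synth[7])
    write_tsv(data.frame(gene_id = names(cohort$truth$category_of_lncrna),
                         label = unname(cohort$truth$category_of_lncrna)),
              files$synth[8])
    write_tsv(cohort$truth$planted_assoc, files$synth[9])
    cfg <- config$synth
    write_tsv(data.frame(key = names(cfg),
                         value = vapply(cfg, function(x)
                           paste(format(x), collapse = ","), "")),
              files$synth[10])
  }

  genes <- read_gene_annotation(files$synth[1])
  manifest <- read_probe_manifest(files$synth[2])
  beta <- read_beta_matrix(files$synth[3])
  signature <- read_signature_matrix(files$synth[4])
  surv <- read_tsv(files$synth[5])
  pathways <- read_pathway_table(files$synth[6])

  ## stage 2: promoter methylation and categorization --------------------
  if (!stage_done("categorize")) {
    retained <- filter_probes(manifest)
    lnc <- genes[genes$biotype == "lncRNA", ]
    promoters <- promoter_of(lnc, flank = config$flank)
    mapping <- map_probes_to_promoters(retained, promoters)
    pm <- suppressWarnings(summarize_promoter(beta, mapping))
    cats <- categorize(pm, hyper = config$hyper, hypo = config$hypo,
                       sample_fraction = config$sample_fraction)
    write_tsv(pm, files$categorize[1], rownames = "id")
    write_tsv(cats, files$categorize[2])
  }
  pm <- as.matrix(read_tsv(files$categorize[1], rownames = "id"))
  cats <- read_tsv(files$categorize[2])

  ## stage 3: consensus subtyping ----------------------------------------
  if (!stage_done("cluster")) {
    retained <- filter_probes(manifest)
    promoters <- promoter_of(genes[genes$biotype == "lncRNA", ],
                             flank = config$flank)
    mapping <- map_probes_to_promoters(retained, promoters)
    lnc_probes <- intersect(unique(unlist(mapping)), colnames(beta))
    top <- select_variable_probes(beta[, lnc_probes, drop = FALSE],
                                  config$top_fraction)
    cc <- consensus_cluster(beta[, top, drop = FALSE],
                            k_range = config$k_range,
                            iterations = config$iterations,
                            resample = config$resample,
                            seed = derive_seed(config$seed, "cluster"))
    write_tsv(data.frame(sample_id = rownames(beta),
                         cluster = unname(cc$assignment)),
              files$cluster[1])
    write_tsv(data.frame(k = names(cc$pac), pac = unname(cc$pac),
                         chosen = as.integer(names(cc$pac)) == cc$chosen_k),
              files$cluster[2])
    write_tsv(cc$consensus[[as.character(cc$chosen_k)]], files$cluster[3],
              rownames = "id")
    write_tsv(sample_correlation(pm), files$cluster[4], rownames = "id")
  }
  assign_df <- read_tsv(files$cluster[1])
  clusters <- stats::setNames(assign_df$cluster, assign_df$sample_id)

  ## stage 4: deconvolution ----------------------------------------------
  if (!stage_done("deconvolve")) {
    fr <- deconvolve(beta, signature, method = config$deconv_method)
    seed0 <- derive_seed(config$seed, "deconvolve")
    fr$perm_p <- vapply(seq_len(nrow(beta)), function(i)
      permutation_p(beta[i, ], signature, n_perm = config$n_perm,
                    seed = seed0 + i, method = config$deconv_method)$p,
      numeric(1))
    write_tsv(fr, files$deconvolve[1], rownames = "sample_id")
    fb <- fractions_by_cluster(fr, clusters)
    write_tsv(fb$anova, files$deconvolve[2])
  }
  fr <- read_tsv(files$deconvolve[1], rownames = "sample_id")
  fractions <- as.matrix(fr[, setdiff(names(fr),
                                      c("rmse", "corr", "perm_p"))])

  ## stage 5: immune-lncRNA association ----------------------------------
  if (!stage_done("immune_lncrna")) {
    assoc <- suppressWarnings(
      spearman_assoc(pm, fractions, clusters,
                     rho_threshold = config$rho_threshold,
                     alpha = config$alpha, min_cluster = config$min_cluster))
    called <- unique(assoc$gene_id[assoc$called])
    enr <- if (length(called) > 0 && length(called) < length(unique(cats$gene_id)))
      category_enrichment(called, cats)
    else data.frame(category = character(0), n_called = integer(0),
                    n_uncalled = integer(0), odds_ratio = numeric(0),
                    p = numeric(0), degenerate = logical(0))
    links <- link_pathways(genes[genes$biotype == "lncRNA", ],
                           genes[genes$biotype == "protein_coding", ],
                           pathways, window = config$window)
    counts <- count_pathways(links, called)
    big <- names(table(clusters))[table(clusters) >= 2]
    keep <- rownames(pm)[clusters[rownames(pm)] %in% big]
    dm <- diff_methylation(pm[keep, , drop = FALSE], clusters[keep],
                           delta_threshold = config$delta_threshold,
                           alpha = config$alpha)
    write_tsv(assoc, files$immune_lncrna[1])
    write_tsv(enr, files$immune_lncrna[2])
    links_flat <- links
    links_flat$pathways <- vapply(links$pathways, paste, "", collapse = ",")
    write_tsv(links_flat, files$immune_lncrna[3])
    write_tsv(counts, files$immune_lncrna[4])
    write_tsv(dm, files$immune_lncrna[5])
  }
  dm <- read_tsv(files$immune_lncrna[5])

  ## stage 6: survival ----------------------------------------------------
  if (!stage_done("survival")) {
    surv$lncrna_cluster <- clusters[surv$sample_id]
    lr <- nested_cox_lr(surv)
    top_gene <- dm$gene_id[which.max(abs(dm$delta))]
    values <- pm[surv$sample_id, top_gene]
    cp <- optimal_cutpoint(values, surv$time, surv$event,
                           min_prop = config$min_prop)
    lrt <- logrank_test(cp$groups, surv$time, surv$event)
    write_tsv(lr, files$survival[1])
    write_tsv(data.frame(gene_id = top_gene, cutpoint = cp$cutpoint,
                         max_stat = cp$max_stat,
                         logrank_chisq = lrt$statistic, logrank_p = lrt$p),
              files$survival[2])
    write_tsv(km_coordinates(cp$groups[surv$sample_id], surv$time,
                             surv$event),
              files$survival[3])
  }

  all_files <- unlist(files, use.names = FALSE)
  manifest_df <- data.frame(
    stage = rep(names(files), lengths(files)),
    file = basename(all_files),
    md5 = unname(tools::md5sum(all_files)),
    stringsAsFactors = FALSE)
  write_tsv(manifest_df, file.path(outdir, "run_manifest.tsv"))
  invisible(manifest_df)
}
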