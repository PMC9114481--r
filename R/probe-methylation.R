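#' Filter methylation probes by manifest exclusion flags
#'
#' Removes probes on the sex chromosomes, probes overlapping a SNP, probes
#' not mapping uniquely to the genome, and probes absent from the EPIC
#' array — the standard cross-study filter set for 450K data. The flags are
#' manifest annotations, not recomputed from external databases.
#'
#' @param manifest probe data frame with logical columns `chrXY`,
#'   `snp_overlap`, `non_unique`, `not_on_epic`.
#' @return the retained rows, in input order, with a `filter_report`
#'   attribute counting removals per flag (a probe carrying several flags
#'   is removed once but counted under each flag).
#' @export
filter_probes <- function(manifest) {
  if (nrow(manifest) == 0) stop("empty manifest")
  flags <- c("chrXY", "snp_overlap", "non_unique", "not_on_epic")
  missing_cols <- setdiff(flags, names(manifest))
  if (length(missing_cols))
    stop("manifest lacks flag columns: ", paste(missing_cols, collapse = ", "))
  flag_mat <- as.matrix(manifest[, flags])
  mode(flag_mat) <- "logical"
  drop <- rowSums(flag_mat, na.rm = TRUE) > 0
  report <- c(colSums(flag_mat, na.rm = TRUE),
              total_removed = sum(drop), retained = sum(!drop))
  if (all(drop)) warning("all probes removed by filters")
  out <- manifest[!drop, , drop = FALSE]
  attr(out, "filter_report") <- report
  out
}

#' Map probes to promoter intervals
#'
#' A probe is assigned to every promoter whose half-open interval
#' `[start, end)` contains its position; probes inside overlapping
#' promoters are assigned to each of them. Overlap detection uses
#' interval trees via \pkg{IRanges}.
#'
#' @param probes filtered manifest (`probe_id`, `chrom`, `pos`).
#' @param promoters output of [promoter_of()].
#' @return named list, gene id -> character vector of probe ids; genes with
#'   no probes are omitted.
#' @export
map_probes_to_promoters <- function(probes, promoters) {
  shared <- intersect(unique(probes$chrom), unique(promoters$chrom))
  if (length(shared) == 0)
    stop("no shared chromosome names between manifest (",
         paste(unique(probes$chrom), collapse = ","), ") and annotation (",
         paste(unique(promoters$chrom), collapse = ","), ")")
  out <- list()
  for (chr in shared) {
    pr <- probes[probes$chrom == chr, ]
    pm <- promoters[promoters$chrom == chr, ]
    if (nrow(pr) == 0 || nrow(pm) == 0) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(start = pr$pos + 1L, width = 1L),
      IRanges::IRanges(start = pm$start + 1L, end = pm$end))
    if (length(hits) == 0) next
    m <- split(pr$probe_id[S4Vectors::queryHits(hits)],
               pm$gene_id[S4Vectors::subjectHits(hits)])
    out <- c(out, m)
  }
  out[order(names(out))]
}

#' Summarize promoter methylation as mean probe beta
#'
#' Promoter methylation of a gene in a sample is the arithmetic mean of the
#' non-missing beta values of the probes mapped to its promoter.
#'
#' @param beta samples x probes matrix in `[0, 1]` (NA allowed).
#' @param mapping gene -> probe ids, from [map_probes_to_promoters()].
#' @return samples x genes matrix with a `probes_per_gene` attribute.
#'   Genes whose probes are all absent from `beta` are dropped with a
#'   warning; a sample with all probes missing gets `NA`.
#' @export
summarize_promoter <- function(beta, mapping) {
  mapping <- lapply(mapping, intersect, colnames(beta))
  empty <- lengths(mapping) == 0
  if (any(empty)) {
    warning(sum(empty), " gene(s) dropped: no probes present in the matrix")
    mapping <- mapping[!empty]
  }
  if (length(mapping) == 0) stop("no gene has probes in the beta matrix")
  pm <- vapply(mapping, function(p) {
    rowMeans(beta[, p, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(beta)))
  pm[is.nan(pm)] <- NA_real_
  pm <- matrix(pm, nrow = nrow(beta),
               dimnames = list(rownames(beta), names(mapping)))
  attr(pm, "probes_per_gene") <- mapping
  pm
}

#' Categorize lncRNAs by promoter methylation
#'
#' Three-way rule over the cohort: a gene is *hyper*-methylated when its
#' promoter beta exceeds `hyper` in more than `sample_fraction` of samples,
#' *hypo*-methylated when below `hypo` in more than `sample_fraction`, and
#' *inter*-methylated otherwise. All inequalities are strict, and fractions
#' are computed over non-missing samples per gene.
#'
#' @param pm samples x genes promoter methylation matrix.
#' @param hyper,hypo beta thresholds (defaults 0.7 and 0.3).
#' @param sample_fraction required sample fraction (default 0.8).
#' @param groups optional sample grouping vector (e.g. cancer type); when
#'   given, the rule is applied within each group and a `group` column added.
#' @return data frame: `gene_id`, `label` (`hyper`/`hypo`/`inter`, `NA` when
#'   no non-missing sample), `frac_above`, `frac_below`, `n_samples`
#'   (non-missing count), and `group` if requested.
#' @export
categorize <- function(pm, hyper = 0.7, hypo = 0.3, sample_fraction = 0.8,
                       groups = NULL) {
  stopifnot(nrow(pm) >= 1, hyper > hypo)
  if (!is.null(groups)) {
    stopifnot(length(groups) == nrow(pm))
    res <- lapply(split(seq_len(nrow(pm)), groups), function(idx) {
      categorize(pm[idx, , drop = FALSE], hyper, hypo, sample_fraction)
    })
    out <- do.call(rbind, Map(function(d, g) cbind(d, group = g),
                              res, names(res)))
    rownames(out) <- NULL
    return(out)
  }
  n_obs <- colSums(!is.na(pm))
  frac_above <- colSums(pm > hyper, na.rm = TRUE) / n_obs
  frac_below <- colSums(pm < hypo, na.rm = TRUE) / n_obs
  label <- ifelse(frac_above > sample_fraction, "hyper",
                  ifelse(frac_below > sample_fraction, "hypo", "inter"))
  label[n_obs == 0] <- NA_character_
  if (any(n_obs == 0))
    warning(sum(n_obs == 0), " gene(s) unclassifiable: no non-missing samples")
  data.frame(gene_id = colnames(pm), label = label,
             frac_above = ifelse(n_obs == 0, NA, frac_above),
             frac_below = ifelse(n_obs == 0, NA, frac_below),
             n_samples = n_obs, row.names = NULL, stringsAsFactors = FALSE)
}
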