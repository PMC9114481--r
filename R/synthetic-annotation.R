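#' Generate a toy gene annotation and probe manifest
#'
#' Lays lncRNA and protein-coding genes along one synthetic chromosome.
#' Some protein-coding genes are placed within 10 kb of a lncRNA (so
#' proximity-based pathway linkage has known positives), others well beyond.
#' Gene spacing guarantees that the 4-kb promoters centered on the
#' strand-aware TSSs never overlap. Each promoter receives on average
#' `probes_per_promoter` CpG probes placed uniformly within it, and a
#' configurable fraction of probes carries each exclusion flag.
#'
#' @param config a [synthetic_config()].
#' @param chrom_length optional declared chromosome length; an error is
#'   raised if the layout does not fit.
#' @return A list with
#'   \describe{
#'     \item{genes}{data frame: `gene_id`, `biotype`, `chrom`, `strand`,
#'       `start`, `end` (0-based half-open), `exon_count`.}
#'     \item{probes}{probe manifest: `probe_id`, `chrom`, `pos` (0-based),
#'       logical flag columns `chrXY`, `snp_overlap`, `non_unique`,
#'       `not_on_epic`, and `gene_id` of the promoter each probe was
#'       planted in.}
#'     \item{linkage}{planted lncRNA-PCG proximity truth: `lncrna_id`,
#'       `pcg_id`, `gap` (bases between interval hulls), `within_10kb`.}
#'     \item{chrom_length}{length of the synthetic chromosome.}
#'   }
#' @export
generate_annotation <- function(config, chrom_length = NULL) {
  validate_synthetic_config(config)
  set.seed(derive_seed(config$seed, "annotation"))

  n_lnc <- config$n_lncrna
  n_pcg <- config$n_pcg

  # interleave: each lncRNA may be followed by one PCG, near (<10 kb) or far
  ids <- character(0); biotype <- character(0)
  start <- numeric(0); end <- numeric(0)
  near <- logical(0)          # per PCG: was it placed within 10 kb?
  pair_lnc <- character(0)    # per PCG: the preceding lncRNA

  cursor <- 5000
  pcg_left <- n_pcg
  lnc_ids <- sprintf("LNC%05d", seq_len(n_lnc))
  pcg_ids <- sprintf("PCG%05d", seq_len(n_pcg))
  pcg_i <- 0
  for (i in seq_len(n_lnc)) {
    len <- round(stats::runif(1, 1000, 3000))
    ids <- c(ids, lnc_ids[i]); biotype <- c(biotype, "lncRNA")
    start <- c(start, cursor); end <- c(end, cursor + len)
    cursor <- cursor + len
    if (pcg_left > 0 && pcg_i < n_pcg) {
      is_near <- stats::runif(1) < 0.5
      gap <- if (is_near) round(stats::runif(1, 4000, 9500))
             else round(stats::runif(1, 12000, 20000))
      plen <- round(stats::runif(1, 1000, 3000))
      pcg_i <- pcg_i + 1
      ids <- c(ids, pcg_ids[pcg_i]); biotype <- c(biotype, "protein_coding")
      start <- c(start, cursor + gap); end <- c(end, cursor + gap + plen)
      near <- c(near, is_near); pair_lnc <- c(pair_lnc, lnc_ids[i])
      cursor <- cursor + gap + plen
      pcg_left <- pcg_left - 1
    }
    cursor <- cursor + round(stats::runif(1, 15000, 25000))
  }
  while (pcg_i < n_pcg) {  # leftover PCGs, placed far from everything
    plen <- round(stats::runif(1, 1000, 3000))
    pcg_i <- pcg_i + 1
    ids <- c(ids, pcg_ids[pcg_i]); biotype <- c(biotype, "protein_coding")
    start <- c(start, cursor); end <- c(end, cursor + plen)
    near <- c(near, FALSE); pair_lnc <- c(pair_lnc, NA_character_)
    cursor <- cursor + plen + round(stats::runif(1, 15000, 25000))
  }
  total_len <- cursor + 5000
  if (!is.null(chrom_length)) {
    if (chrom_length < total_len)
      stop("chromosome length ", chrom_length,
           " too short for layout needing ", total_len, " bases")
    total_len <- chrom_length
  }

  genes <- data.frame(gene_id = ids, biotype = biotype, chrom = "chr1",
                      strand = sample(c("+", "-"), length(ids), replace = TRUE),
                      start = start, end = end,
                      exon_count = ifelse(biotype == "lncRNA",
                                          stats::rpois(length(ids), 1) + 1L,
                                          stats::rpois(length(ids), 7) + 1L),
                      stringsAsFactors = FALSE)

  proms <- promoter_of(genes, chrom_length = total_len)
  n_probes <- pmax(1L, stats::rpois(nrow(proms), config$probes_per_promoter))
  probe_gene <- rep(proms$gene_id, n_probes)
  pos <- unlist(mapply(function(s, e, k) {
    sort(floor(stats::runif(k, s, e)))
  }, proms$start, proms$end, n_probes, SIMPLIFY = FALSE))
  m <- length(pos)
  probes <- data.frame(probe_id = sprintf("cg%07d", seq_len(m)),
                       chrom = "chr1", pos = pos,
                       chrXY = stats::runif(m) < config$flag_fraction,
                       snp_overlap = stats::runif(m) < config$flag_fraction,
                       non_unique = stats::runif(m) < config$flag_fraction,
                       not_on_epic = stats::runif(m) < config$flag_fraction,
                       gene_id = probe_gene,
                       stringsAsFactors = FALSE)

  keep <- !is.na(pair_lnc)
  glu <- genes[match(pair_lnc[keep], genes$gene_id), ]
  gpc <- genes[match(ids[biotype == "protein_coding"][seq_len(sum(keep))],
                     genes$gene_id), ]
  # paired PCG always starts after its lncRNA ends
  gap <- pmax(0, gpc$start - glu$end)
  linkage <- data.frame(lncrna_id = glu$gene_id, pcg_id = gpc$gene_id,
                        gap = gap, within_10kb = gap <= 10000,
                        stringsAsFactors = FALSE)

  list(genes = genes, probes = probes, linkage = linkage,
       chrom_length = total_len)
}
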