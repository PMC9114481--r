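#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (via [stats::p.adjust()]):
#' sort ascending, take the running minimum of `p * m / rank` from the
#' largest rank down, cap at 1, and return in input order. A Bonferroni
#' option is provided for users who prefer family-wise control.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param method `"BH"` (default) or `"bonferroni"`.
#' @return adjusted p-values, same order as the input.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_adjust <- function(p, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = method)
}

#' Infiltration-correlated lncRNAs by cluster
#'
#' Within each subtype, computes the Spearman correlation (average-rank
#' ties) between every lncRNA's promoter methylation and every cell type's
#' infiltration fraction, with the p-value from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))`. Adjustment is applied across
#' lncRNAs within each (cluster, cell type) stratum. A lncRNA is called
#' infiltration-related when `|rho| > rho_threshold` and adjusted
#' `p < alpha` (both conditions required).
#'
#' @param pm samples x lncRNAs promoter methylation matrix.
#' @param fractions samples x cell-types fraction matrix (same sample order
#'   as `pm`, matched by rownames when present).
#' @param clusters named vector sample -> cluster; clusters with fewer than
#'   `min_cluster` samples are skipped with a warning.
#' @param rho_threshold correlation magnitude threshold (default 0.3).
#' @param alpha adjusted-p threshold (default 0.05).
#' @param min_cluster minimum cluster size (default 10).
#' @param adjust `"BH"` or `"bonferroni"`.
#' @return data frame: `cluster`, `gene_id`, `cell_type`, `rho`, `p_raw`,
#'   `p_adj`, `called`. Constant methylation or fractions within a cluster
#'   yield `NA` rho (never called).
#' @export
spearman_assoc <- function(pm, fractions, clusters, rho_threshold = 0.3,
                           alpha = 0.05, min_cluster = 10, adjust = "BH") {
  if (!is.null(rownames(fractions)) && !is.null(rownames(pm)))
    fractions <- fractions[rownames(pm), , drop = FALSE]
  cl <- if (!is.null(rownames(pm)) && !is.null(names(clusters)))
    clusters[rownames(pm)] else clusters
  sizes <- table(cl)
  skipped <- names(sizes)[sizes < min_cluster]
  if (length(skipped))
    warning("skipping cluster(s) with < ", min_cluster, " samples: ",
            paste(skipped, collapse = ", "))
  out <- list()
  for (g in setdiff(names(sizes), skipped)) {
    idx <- which(cl == g)
    n <- length(idx)
    rho <- suppressWarnings(
      stats::cor(pm[idx, , drop = FALSE], fractions[idx, , drop = FALSE],
                 method = "spearman", use = "everything"))
    tt <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
    p_raw <- 2 * stats::pt(-abs(tt), df = n - 2)
    p_raw[abs(rho) >= 1] <- 0
    p_adj <- apply(p_raw, 2, bh_adjust, method = adjust)
    called <- !is.na(rho) & abs(rho) > rho_threshold & p_adj < alpha
    out[[g]] <- data.frame(cluster = g,
                           gene_id = rep(rownames(rho), ncol(rho)),
                           cell_type = rep(colnames(rho), each = nrow(rho)),
                           rho = as.vector(rho), p_raw = as.vector(p_raw),
                           p_adj = as.vector(p_adj),
                           called = as.vector(called),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Enrichment of methylation categories among called lncRNAs
#'
#' For each category, a Fisher exact test on the 2x2 table of category
#' membership against called status (two-sided). Degenerate tables (an
#' empty margin) return p = 1 with a flag.
#'
#' @param called character vector of called lncRNA ids.
#' @param categories data frame from [categorize()] (`gene_id`, `label`);
#'   its genes define the universe.
#' @return data frame: `category`, `n_called`, `n_uncalled`, `odds_ratio`,
#'   `p`, `degenerate`.
#' @export
category_enrichment <- function(called, categories) {
  categories <- categories[!is.na(categories$label), ]
  universe <- categories$gene_id
  is_called <- universe %in% called
  if (all(is_called) || !any(is_called))
    stop("need at least one called and one uncalled gene in the universe")
  out <- do.call(rbind, lapply(unique(categories$label), function(lab) {
    in_cat <- categories$label == lab
    tab <- table(factor(in_cat, c(TRUE, FALSE)),
                 factor(is_called, c(TRUE, FALSE)))
    degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
    ft <- stats::fisher.test(tab)
    data.frame(category = lab, n_called = tab[1, 1], n_uncalled = tab[1, 2],
               odds_ratio = unname(ft$estimate),
               p = if (degenerate) 1 else ft$p.value,
               degenerate = degenerate, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Link lncRNAs to nearby protein-coding genes and their pathways
#'
#' A protein-coding gene is linked to a lncRNA when the gap between their
#' interval hulls is at most `window` bases (0 when the intervals overlap).
#' `mode = "tss"` instead measures the absolute TSS-to-TSS distance. Genes
#' absent from the pathway table are linked with an empty pathway set.
#'
#' @param lncrnas,pcgs gene data frames (`gene_id`, `chrom`, `strand`,
#'   `start`, `end`), same coordinate convention.
#' @param pathway_table data frame (`gene_id`, `pathway`), one row per
#'   membership; e.g. an immune pathway panel.
#' @param window maximum distance in bases (default 10000).
#' @param mode `"hull"` (default) or `"tss"`.
#' @return data frame: `lncrna_id`, `pcg_id`, `distance`, `pathways`
#'   (list column of pathway names).
#' @export
link_pathways <- function(lncrnas, pcgs, pathway_table = NULL,
                          window = 10000, mode = c("hull", "tss")) {
  mode <- match.arg(mode)
  if (is.null(pathway_table) || nrow(pathway_table) == 0) {
    warning("empty pathway table: all links carry empty pathway sets")
    pathway_table <- data.frame(gene_id = character(0),
                                pathway = character(0))
  }
  links <- list()
  for (i in seq_len(nrow(lncrnas))) {
    l <- lncrnas[i, ]
    same <- pcgs[pcgs$chrom == l$chrom, , drop = FALSE]
    if (nrow(same) == 0) next
    dist <- if (mode == "hull") {
      pmax(0, same$start - l$end, l$start - same$end)
    } else {
      ltss <- if (l$strand == "+") l$start else l$end
      ptss <- ifelse(same$strand == "+", same$start, same$end)
      abs(ptss - ltss)
    }
    hit <- which(dist <= window)
    if (length(hit) == 0) next
    links[[length(links) + 1L]] <- data.frame(
      lncrna_id = l$gene_id, pcg_id = same$gene_id[hit],
      distance = dist[hit], stringsAsFactors = FALSE)
  }
  if (length(links) == 0)
    return(data.frame(lncrna_id = character(0), pcg_id = character(0),
                      distance = numeric(0),
                      pathways = I(list())))
  out <- do.call(rbind, links)
  out$pathways <- I(lapply(out$pcg_id, function(g)
    unique(pathway_table$pathway[pathway_table$gene_id == g])))
  rownames(out) <- NULL
  out
}

#' Count distinct pathways reachable from each called lncRNA
#'
#' @param links output of [link_pathways()].
#' @param called character vector of called lncRNA ids (e.g. from
#'   [spearman_assoc()]).
#' @return data frame: `lncrna_id`, `n_pathways` (distinct pathways over
#'   all linked protein-coding genes; 0 when none of them is annotated).
#' @export
count_pathways <- function(links, called) {
  counts <- vapply(called, function(g) {
    pw <- unlist(links$pathways[links$lncrna_id == g])
    length(unique(pw))
  }, integer(1))
  data.frame(lncrna_id = called, n_pathways = unname(counts),
             stringsAsFactors = FALSE)
}

#' One-vs-rest differential promoter methylation
#'
#' For every (cluster, gene), a Welch two-sample t-test of the cluster's
#' samples against all remaining samples. `delta` is mean(cluster) minus
#' mean(rest); a gene is called differentially methylated in a cluster when
#' `|delta| > delta_threshold` and raw `p < alpha` (the raw p-value is the
#' convention for this screen; associations, in contrast, use adjusted p).
#'
#' @param pm samples x genes promoter methylation matrix.
#' @param clusters named vector sample -> cluster; every cluster and its
#'   complement must have >= 2 samples.
#' @param delta_threshold beta-difference threshold (default 0.2).
#' @param alpha p-value threshold (default 0.05).
#' @return data frame: `cluster`, `gene_id`, `delta`, `p`, `called`.
#'   When both groups are constant, p is 1 for equal means and 0 otherwise.
#' @export
diff_methylation <- function(pm, clusters, delta_threshold = 0.2,
                             alpha = 0.05) {
  cl <- clusters[rownames(pm)]
  out <- list()
  for (g in sort(unique(cl))) {
    in_g <- cl == g
    if (sum(in_g) < 2 || sum(!in_g) < 2)
      stop("cluster ", g, " or its complement has < 2 samples")
    x <- pm[in_g, , drop = FALSE]; y <- pm[!in_g, , drop = FALSE]
    n1 <- colSums(!is.na(x)); n2 <- colSums(!is.na(y))
    m1 <- colMeans(x, na.rm = TRUE); m2 <- colMeans(y, na.rm = TRUE)
    v1 <- apply(x, 2, stats::var, na.rm = TRUE)
    v2 <- apply(y, 2, stats::var, na.rm = TRUE)
    se2 <- v1 / n1 + v2 / n2
    tt <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    p <- 2 * stats::pt(-abs(tt), df)
    zerovar <- se2 == 0
    p[zerovar] <- ifelse(m1[zerovar] == m2[zerovar], 1, 0)
    delta <- m1 - m2
    out[[as.character(g)]] <- data.frame(
      cluster = g, gene_id = colnames(pm), delta = unname(delta),
      p = unname(p), called = unname(abs(delta) > delta_threshold &
                                       p < alpha),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
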