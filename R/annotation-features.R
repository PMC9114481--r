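#' Derive strand-aware promoter intervals
#'
#' The promoter is the window of `2 * flank` bases centered on the
#' transcription start site: gene `start` on the plus strand, gene `end` on
#' the minus strand. Coordinates are 0-based half-open; the interval is
#' clipped to `[0, chrom_length)`.
#'
#' @param genes data frame with columns `gene_id`, `chrom`, `strand`
#'   (`"+"`/`"-"`), `start`, `end` (0-based half-open).
#' @param flank bases on each side of the TSS (default 2000, i.e. a 4-kb
#'   promoter).
#' @param chrom_length chromosome length used for clipping; `Inf` disables
#'   right clipping. May be a single value or a named vector by chromosome.
#' @return data frame with `gene_id`, `chrom`, `start`, `end`, `tss`.
#' @examples
#' g <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
#'                 start = 10000, end = 12000)
#' promoter_of(g)  # [8000, 12000)
#' @export
promoter_of <- function(genes, flank = 2000, chrom_length = Inf) {
  stopifnot(all(c("gene_id", "chrom", "strand", "start", "end") %in%
                  names(genes)),
            all(genes$start < genes$end), flank > 0)
  tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  len <- if (!is.null(names(chrom_length)))
    unname(chrom_length[genes$chrom]) else chrom_length
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             start = pmax(0, tss - flank), end = pmin(len, tss + flank),
             tss = tss, stringsAsFactors = FALSE)
}

#' GC content of nucleotide sequences
#'
#' Fraction (G + C) / (A + C + G + T); `N` bases are excluded from both
#' numerator and denominator. Returns `NA` for an all-N sequence.
#'
#' @param seq character vector of sequences over `A,C,G,T,N`.
#' @return numeric vector of GC fractions in `[0, 1]`.
#' @export
gc_content <- function(seq) {
  if (any(!nzchar(seq))) stop("empty sequence")
  seq <- toupper(seq)
  count <- function(s, chars) {
    sum(strsplit(s, "", fixed = TRUE)[[1]] %in% chars)
  }
  vapply(seq, function(s) {
    gc <- count(s, c("G", "C"))
    n <- count(s, c("A", "C", "G", "T"))
    if (n == 0) NA_real_ else gc / n
  }, numeric(1), USE.NAMES = FALSE)
}

#' Normalized CpG ratio (observed / expected CpG)
#'
#' Observed CpG fraction is the number of `CG` dinucleotides over the
#' `L - 1` overlapping dinucleotide windows; expected is
#' `(GC content / 2)^2`, the classic CpG observed/expected convention for
#' CpG-island detection. Returns `NA` when the expected value is zero
#' (GC-free sequence).
#'
#' @param seq character vector of sequences, each of length >= 2.
#' @return numeric vector of O/E ratios.
#' @examples
#' normalized_cpg("CGCGCG")  # 0.6 / 0.25 = 2.4
#' normalized_cpg("ACGT")    # (1/3) / 0.0625 = 16/3
#' @export
normalized_cpg <- function(seq) {
  if (any(nchar(seq) < 2)) stop("sequences must have length >= 2")
  seq <- toupper(seq)
  obs <- vapply(seq, function(s) {
    hits <- gregexpr("CG", s, fixed = TRUE)[[1]]
    n_cg <- if (hits[1] == -1L) 0L else length(hits)
    n_cg / (nchar(s) - 1)
  }, numeric(1), USE.NAMES = FALSE)
  expected <- (gc_content(seq) / 2)^2
  ifelse(is.na(expected) | expected == 0, NA_real_, obs / expected)
}

#' Mean conservation score over a promoter
#'
#' Averages per-base conservation scores (e.g. phastCons) falling inside a
#' promoter interval. Bases without a score, or with `NA` scores, are
#' excluded from both numerator and denominator.
#'
#' @param track data frame with columns `chrom`, `pos` (0-based), `score`.
#' @param promoter one row of [promoter_of()] output (or any list with
#'   `chrom`, `start`, `end`).
#' @return mean score, or `NA` if no scored base falls in the promoter.
#' @export
mean_conservation <- function(track, promoter) {
  stopifnot(all(c("chrom", "pos", "score") %in% names(track)))
  inside <- track$chrom == promoter$chrom &
    track$pos >= promoter$start & track$pos < promoter$end
  s <- track$score[inside]
  s <- s[!is.na(s)]
  if (length(s) == 0) NA_real_ else mean(s)
}

#' Compare a feature across methylation categories
#'
#' Runs a two-sample test for every pair of categories. The
#' Kolmogorov-Smirnov test is the convention for distributional features
#' (GC content, normalized CpG); the Wilcoxon rank-sum test for count-like
#' or score features (conservation, CpG counts, exon counts). The reported
#' Wilcoxon statistic is the Mann-Whitney U as returned by
#' [stats::wilcox.test()].
#'
#' @param values numeric vector, one value per gene.
#' @param categories character/factor vector of category labels, same length.
#' @param test `"ks"` or `"wilcoxon"`.
#' @return data frame with `group1`, `group2`, `statistic`, `p`. Category
#'   pairs where either group has fewer than 2 members are skipped with a
#'   warning.
#' @export
compare_feature_by_category <- function(values, categories,
                                        test = c("ks", "wilcoxon")) {
  test <- match.arg(test)
  stopifnot(length(values) == length(categories))
  keep <- !is.na(values) & !is.na(categories)
  values <- values[keep]; categories <- as.character(categories)[keep]
  groups <- split(values, categories)
  if (length(groups) < 2) stop("need at least 2 categories")
  small <- names(groups)[lengths(groups) < 2]
  if (length(small)) {
    warning("skipping categories with < 2 members: ",
            paste(small, collapse = ", "))
    groups <- groups[lengths(groups) >= 2]
  }
  pairs <- utils::combn(names(groups), 2)
  res <- apply(pairs, 2, function(pr) {
    x <- groups[[pr[1]]]; y <- groups[[pr[2]]]
    ht <- if (test == "ks") suppressWarnings(stats::ks.test(x, y))
          else suppressWarnings(stats::wilcox.test(x, y))
    c(statistic = unname(ht$statistic), p = ht$p.value)
  })
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
             statistic = res["statistic", ], p = res["p", ],
             stringsAsFactors = FALSE)
}
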