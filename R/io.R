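#' Read gene annotation from a BED-like TSV or a GTF file
#'
#' The BED-like TSV is the package's native interchange format: columns
#' `gene_id`, `biotype`, `chrom`, `strand`, `start`, `end` (0-based
#' half-open), `exon_count`. GTF files (1-based inclusive) are read through
#' \pkg{rtracklayer} and converted on ingest: gene records provide the
#' intervals, `exon_count` is the number of exon records per gene.
#'
#' @param path annotation file.
#' @param format `"tsv"` (default) or `"gtf"`.
#' @return gene data frame in the native 0-based half-open convention.
#' @export
read_gene_annotation <- function(path, format = c("tsv", "gtf")) {
  format <- match.arg(format)
  if (format == "tsv") {
    genes <- read_tsv(path)
    need <- c("gene_id", "biotype", "chrom", "strand", "start", "end")
    if (!all(need %in% names(genes)))
      stop("annotation TSV lacks columns: ",
           paste(setdiff(need, names(genes)), collapse = ", "))
    if (is.null(genes$exon_count)) genes$exon_count <- 1L
    return(genes)
  }
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading GTF requires the rtracklayer package")
  gr <- rtracklayer::import(path, format = "gtf")
  meta <- S4Vectors::mcols(gr)
  is_gene <- meta$type == "gene"
  is_exon <- meta$type == "exon"
  exon_counts <- table(meta$gene_id[is_exon])
  gid <- meta$gene_id[is_gene]
  data.frame(gene_id = gid,
             biotype = ifelse(meta$gene_type[is_gene] == "protein_coding",
                              "protein_coding", "lncRNA"),
             chrom = as.character(GenomicRanges::seqnames(gr)[is_gene]),
             strand = as.character(GenomicRanges::strand(gr)[is_gene]),
             start = GenomicRanges::start(gr)[is_gene] - 1L,  # to 0-based
             end = GenomicRanges::end(gr)[is_gene],
             exon_count = as.integer(
               ifelse(gid %in% names(exon_counts), exon_counts[gid], 1L)),
             stringsAsFactors = FALSE)
}

#' Read gene sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return named character vector of sequences (names are the FASTA ids).
#' @export
read_sequences <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("reading FASTA requires the Biostrings package")
  s <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(s), sub("\\s.*$", "", names(s)))
}

#' Read a probe manifest TSV
#'
#' Expects `probe_id`, `chrom`, `pos` and the four exclusion-flag columns
#' (`chrXY`, `snp_overlap`, `non_unique`, `not_on_epic`); missing flag
#' columns are added as all-`FALSE`.
#'
#' @param path manifest TSV.
#' @return manifest data frame.
#' @export
read_probe_manifest <- function(path) {
  m <- read_tsv(path)
  need <- c("probe_id", "chrom", "pos")
  if (!all(need %in% names(m)))
    stop("manifest lacks columns: ",
         paste(setdiff(need, names(m)), collapse = ", "))
  for (fl in c("chrXY", "snp_overlap", "non_unique", "not_on_epic"))
    if (is.null(m[[fl]])) m[[fl]] <- FALSE else m[[fl]] <- as.logical(m[[fl]])
  m
}

#' Read a beta matrix TSV with orientation auto-detection
#'
#' Accepts either orientation (samples x probes or probes x samples). When
#' `probe_ids` is given, orientation is detected from which dimension's
#' names overlap the known probe ids (and logged as a message); otherwise
#' rows are assumed to be samples.
#'
#' @param path TSV with header row and row-name column `id`.
#' @param probe_ids optional character vector of known probe ids.
#' @return samples x probes numeric matrix.
#' @export
read_beta_matrix <- function(path, probe_ids = NULL) {
  x <- as.matrix(read_tsv(path, rownames = "id"))
  if (!is.null(probe_ids)) {
    row_hits <- mean(rownames(x) %in% probe_ids)
    col_hits <- mean(colnames(x) %in% probe_ids)
    if (row_hits > col_hits) {
      message("beta matrix read as probes x samples; transposing")
      x <- t(x)
    } else {
      message("beta matrix read as samples x probes")
    }
  }
  x
}

#' Read a cell-type signature matrix TSV
#' @param path TSV with row-name column `probe_id`, one column per cell type.
#' @return probes x cell-types numeric matrix.
#' @export
read_signature_matrix <- function(path) {
  as.matrix(read_tsv(path, rownames = "probe_id"))
}

#' Read an immune pathway gene-set table
#' @param path TSV with columns `gene_id`, `pathway`.
#' @return data frame.
#' @export
read_pathway_table <- function(path) {
  x <- read_tsv(path)
  if (!all(c("gene_id", "pathway") %in% names(x)))
    stop("pathway table needs columns gene_id and pathway")
  x
}
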