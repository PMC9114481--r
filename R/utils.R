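#' @keywords internal
"_PACKAGE"

#' Clip values into the closed unit interval
#' @param x numeric vector.
#' @return `x` with values below 0 set to 0 and above 1 set to 1.
#' @keywords internal
clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Derive a stage-specific seed from a global seed
#'
#' Stage names are hashed (sum of position-weighted character codes) and
#' combined with the global seed modulo 2^31 - 1, so every stage of a
#' pipeline run is independently reproducible from one user-supplied seed.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_len(nchar(stage)))
  as.integer((abs(seed) * 7919 + h) %% (2^31 - 1))
}

#' Write a data frame as TSV with NA encoding
#' @param x data frame or matrix.
#' @param path output file.
#' @param rownames write row names as a leading column with this name;
#'   `NULL` drops them.
#' @export
write_tsv <- function(x, path, rownames = NULL) {
  if (!is.null(rownames)) {
    x <- data.frame(row.names = NULL,
                    stats::setNames(list(rownames(x)), rownames),
                    as.data.frame(x, check.names = FALSE),
                    check.names = FALSE)
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, na = "NA",
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path file path.
#' @param rownames name of the column to use as row names, or `NULL`.
#' @return data frame.
#' @export
read_tsv <- function(path, rownames = NULL) {
  x <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                         na.strings = "NA", check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (!is.null(rownames)) {
    rownames(x) <- x[[rownames]]
    x[[rownames]] <- NULL
  }
  x
}
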