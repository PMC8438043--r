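#' Construct a quantification table
#'
#' A feature-by-sample intensity matrix with provenance: the aggregation
#' level (precursor, peptide, site or protein), feature metadata and sample
#' metadata. Missing values are `NA`; present intensities must be positive.
#'
#' @param mat Numeric matrix, features in rows, samples in columns, with
#'   unique dimnames.
#' @param level One of "precursor", "peptide", "site", "protein".
#' @param features Optional data.frame of feature metadata (row-aligned).
#' @param samples Optional data.frame of sample metadata with a `sample`
#'   column matching `colnames(mat)`.
#' @return An object of class `quant_table`.
#' @export
quant_table <- function(mat, level = c("precursor", "peptide", "site",
                                       "protein"),
                        features = NULL, samples = NULL) {
  level <- match.arg(level)
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  if (anyDuplicated(rownames(mat)) || anyDuplicated(colnames(mat))) {
    stop("feature and sample ids must be unique")
  }
  if (any(mat[!is.na(mat)] <= 0)) stop("present intensities must be > 0")
  structure(list(mat = mat, level = level, features = features,
                 samples = samples),
            class = "quant_table")
}

#' @export
print.quant_table <- function(x, ...) {
  cat(sprintf("quant_table [%s]: %d features x %d samples (%.1f%% missing)\n",
              x$level, nrow(x$mat), ncol(x$mat),
              100 * mean(is.na(x$mat))))
  invisible(x)
}

#' @export
dim.quant_table <- function(x) dim(x$mat)

#' Write a quant table as TSV
#'
#' Feature id in the first column, one column per sample, missing values as
#' empty fields. Sample metadata, if present, goes to a sidecar
#' `<path>.samples.tsv`.
#'
#' @param qt A [quant_table()].
#' @param path Output file.
#' @export
write_quant_table <- function(qt, path) {
  df <- data.frame(feature_id = rownames(qt$mat), qt$mat,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  if (!is.null(qt$samples)) {
    utils::write.table(qt$samples, paste0(path, ".samples.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a quant table written by [write_quant_table()]
#'
#' @param path TSV file.
#' @param level Aggregation level to record.
#' @return A [quant_table()].
#' @export
read_quant_table <- function(path, level = "precursor") {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  samples <- NULL
  side <- paste0(path, ".samples.tsv")
  if (file.exists(side)) samples <- utils::read.delim(side)
  quant_table(mat, level = level, samples = samples)
}
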