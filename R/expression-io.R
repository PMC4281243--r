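# Reading expression tables and sample metadata, replicate averaging and
# sample-level QC correlations.

#' Read a genes x samples FPKM table
#'
#' Expects a UTF-8 TSV with a header row of sample identifiers and the gene
#' identifier in the first column. Gene identifiers are treated as opaque
#' strings. Each failure mode raises a distinct condition class:
#' \code{ts_missing_file}, \code{ts_non_numeric}, \code{ts_duplicate_gene},
#' \code{ts_negative_value}.
#'
#' @param path path to the TSV file.
#' @return Numeric matrix of FPKM values with gene rownames and sample
#'   colnames.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene_id\ts1\ts2", "g1\t1.5\t0", "g2\t3\t4"), tf)
#' readExpressionTable(tf)
#' @export
readExpressionTable <- function(path) {
  if (!file.exists(path))
    tsStop(sprintf("expression table not found: %s", path),
           c("ts_missing_file", "ts_data_error"))
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character",
                          quote = "")
  if (ncol(df) < 2)
    tsStop("expression table needs a gene column and >= 1 sample column",
           "ts_data_error")
  genes <- df[[1]]
  dup <- unique(genes[duplicated(genes)])
  if (length(dup))
    tsStop(sprintf("duplicate gene identifier(s): %s",
                   paste(utils::head(dup, 5), collapse = ", ")),
           c("ts_duplicate_gene", "ts_data_error"))
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- is.na(num) & !is.na(vals)
  if (any(bad) || anyNA(vals))
    tsStop("non-numeric or missing expression value(s) in table",
           c("ts_non_numeric", "ts_data_error"))
  if (any(num < 0))
    tsStop("negative expression value(s) in table",
           c("ts_negative_value", "ts_data_error"))
  dimnames(num) <- list(genes, colnames(vals))
  num
}

#' Read a sample metadata table
#'
#' TSV with columns \code{sample_id}, \code{tissue}, \code{individual}
#' (additional columns are kept as-is).
#'
#' @param path path to the TSV file.
#' @return data.frame of sample records.
#' @export
readSampleMetadata <- function(path) {
  if (!file.exists(path))
    tsStop(sprintf("metadata table not found: %s", path),
           c("ts_missing_file", "ts_data_error"))
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character",
                          quote = "")
  need <- c("sample_id", "tissue", "individual")
  if (!all(need %in% colnames(df)))
    tsStop("metadata needs columns sample_id, tissue, individual",
           "ts_data_error")
  if (anyDuplicated(df$sample_id))
    tsStop("duplicate sample_id in metadata", "ts_data_error")
  if (any(!nzchar(df$tissue)))
    tsStop("empty tissue name in metadata", "ts_data_error")
  df
}

#' Collapse replicate samples to tissue-level mean profiles
#'
#' Computes, for every gene, the arithmetic mean FPKM (on the linear scale)
#' over all samples of each tissue. Tissues are ordered lexicographically.
#'
#' @param x a \linkS4class{TissueExpression}.
#' @param ... unused.
#' @return A \linkS4class{TissueProfile}.
#' @examples
#' m <- matrix(c(4, 1, 6, 3), 1, 4,
#'             dimnames = list("g1", paste0("s", 1:4)))
#' md <- data.frame(sample_id = paste0("s", 1:4),
#'                  tissue = c("kidney", "liver", "kidney", "liver"),
#'                  individual = c("i1", "i1", "i2", "i2"))
#' meanFPKM(averageByTissue(TissueExpression(m, md)))
#' @export
setMethod("averageByTissue", "TissueExpression", function(x, ...) {
  tissue <- as.character(colData(x)$tissue)
  tissues <- sort(unique(tissue))
  fpkm <- assay(x, "fpkm")
  mm <- vapply(tissues, function(t)
    rowMeans(fpkm[, tissue == t, drop = FALSE]),
    numeric(nrow(fpkm)))
  mm <- matrix(mm, nrow = nrow(fpkm),
               dimnames = list(rownames(fpkm), tissues))
  TissueProfile(mm, nSamples = as.integer(table(tissue)[tissues]))
})

#' Pairwise Spearman correlations between samples
#'
#' Rank correlations over all genes for every pair of samples, the standard
#' replicate-quality check for a multi-tissue compendium (replicates of the
#' same tissue are expected near 1, distant tissues such as kidney vs
#' testis substantially lower). Ties receive average ranks. A sample with
#' constant expression has undefined correlations; these are reported as
#' \code{NA} with a warning, never silently as 0. The diagonal is 1.
#'
#' @param x a \linkS4class{TissueExpression} or a numeric genes x samples
#'   matrix.
#' @param ... unused.
#' @return Square symmetric correlation matrix with sample dimnames.
#' @export
setMethod("pairwiseSampleCorrelation", "TissueExpression",
  function(x, ...) pairwiseSampleCorrelation(assay(x, "fpkm")))

#' @rdname pairwiseSampleCorrelation
#' @export
setMethod("pairwiseSampleCorrelation", "matrix", function(x, ...) {
  if (ncol(x) < 2)
    tsStop("need >= 2 samples for pairwise correlation", "ts_data_error")
  if (nrow(x) < 2)
    tsStop("need >= 2 genes for pairwise correlation", "ts_data_error")
  cc <- suppressWarnings(stats::cor(x, method = "spearman"))
  diag(cc) <- 1
  if (anyNA(cc))
    warning("constant sample(s): correlation undefined, reported as NA")
  cc
})

#' log2 with a pseudocount
#'
#' \code{log2(x + pseudocount)}; with the default pseudocount of 1 this
#' maps 0 FPKM to 0 and is monotone increasing, the transform conventionally
#' applied to FPKM before log-scale analyses.
#'
#' @param x non-negative numeric vector.
#' @param pseudocount positive offset, default 1.
#' @return \code{log2(x + pseudocount)}.
#' @examples
#' log2Pseudo(c(0, 1, 15))
#' @export
log2Pseudo <- function(x, pseudocount = 1) {
  if (pseudocount <= 0)
    tsStop("pseudocount must be > 0", "ts_config_error")
  if (any(x < 0, na.rm = TRUE))
    tsStop("negative value passed to log2Pseudo",
           c("ts_negative_value", "ts_data_error"))
  log2(x + pseudocount)
}

#' Write a correlation matrix as a TSV square matrix
#'
#' @param cc square correlation matrix.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeCorrelationMatrix <- function(cc, path) {
  df <- data.frame(sample_id = rownames(cc), cc, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
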